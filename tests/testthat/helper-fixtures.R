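# In-code fixture builders shared across the suite.

specimen_row <- function(id, part, couple, sex, tp) {
  data.frame(sample_id = id, participant_id = part, couple_id = couple,
             sex = sex, timepoint = tp, sample_class = "specimen")
}

control_row <- function(id, class) {
  data.frame(sample_id = id, participant_id = NA, couple_id = NA, sex = NA,
             timepoint = NA, sample_class = class)
}

simple_taxonomy <- function(asv_ids, genus = NULL, species = NULL) {
  n <- length(asv_ids)
  data.frame(asv_id = asv_ids, kingdom = "Bacteria",
             phylum = "unclassified", class = "unclassified",
             order = "unclassified", family = "unclassified",
             genus = genus %||% paste0("Genus", seq_len(n)),
             species = species %||% "unclassified")
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# A tiny 3-ASV x 4-sample cohort: one couple (4 specimens would need 4
# columns), so use 1 couple's female pair + blank + NTC.
tiny_dataset <- function() {
  counts <- matrix(c(5L, 3L, 2L,
                     7L, 0L, 1L,
                     0L, 2L, 0L,
                     1L, 0L, 0L),
                   nrow = 3,
                   dimnames = list(paste0("asv", 1:3),
                                   c("F_b", "F_a", "BL1", "NTC1")))
  md <- rbind(specimen_row("F_b", "P1", "C1", "female", "before"),
              specimen_row("F_a", "P1", "C1", "female", "after"),
              control_row("BL1", "extraction_blank"),
              control_row("NTC1", "no_template_control"))
  cohort_dataset(counts, simple_taxonomy(rownames(counts)), md)
}

# Build a one-couple (or multi-couple) dataset from explicit per-sample
# count vectors. `samples` is a named list: name -> integer vector over a
# shared ASV id set; `meta` the matching metadata rows.
build_dataset <- function(samples, meta, taxonomy = NULL) {
  counts <- do.call(cbind, samples)
  colnames(counts) <- names(samples)
  storage.mode(counts) <- "integer"
  cohort_dataset(counts, taxonomy %||% simple_taxonomy(rownames(counts)),
                 meta)
}

# A random miniature multi-couple cohort on <= n_asvs ASVs; presence is
# sparse so supports differ between samples. Used by the brute-force
# equivalence checks.
random_mini_cohort <- function(n_couples = 2, n_asvs = 20,
                               presence_prob = 0.35) {
  asvs <- sprintf("t%02d", seq_len(n_asvs))
  samples <- list()
  meta <- list()
  for (i in seq_len(n_couples)) {
    cid <- paste0("K", i)
    for (sex in c("female", "male")) {
      for (tp in c("before", "after")) {
        id <- paste(cid, substr(sex, 1, 1), tp, sep = "_")
        x <- stats::rbinom(n_asvs, 1, presence_prob) *
          (1L + stats::rpois(n_asvs, 20))
        if (sum(x) == 0) x[sample(n_asvs, 1)] <- 5L
        samples[[id]] <- as.integer(x)
        meta[[id]] <- specimen_row(id, paste0(cid, substr(sex, 1, 1)),
                                   cid, sex, tp)
      }
    }
  }
  counts <- do.call(cbind, samples)
  rownames(counts) <- asvs
  build_dataset(stats::setNames(asplit(counts, 2), colnames(counts)),
                do.call(rbind, meta),
                simple_taxonomy(asvs))
}

# Observed support set of one sample, recomputed independently.
support_of <- function(dataset, id) {
  rownames(dataset$counts)[dataset$counts[, id] > 0]
}
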