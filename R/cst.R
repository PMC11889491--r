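# Vaginal community state types (CSTs): four of the five canonical classes
# are dominated by a single Lactobacillus species, the fifth is diverse and
# Lactobacillus-poor.
cst_species <- c(I = "Lactobacillus crispatus",
                 II = "Lactobacillus gasseri",
                 III = "Lactobacillus iners",
                 V = "Lactobacillus jensenii")

#' Assign a vaginal community state type
#'
#' Aggregates an ASV profile to species level and applies the dominance
#' rule: the sample is CST I/II/III/V when the corresponding species
#' (*L. crispatus* / *L. gasseri* / *L. iners* / *L. jensenii*) is the
#' single most abundant species and exceeds the dominance threshold;
#' otherwise it is the diverse, Lactobacillus-depleted CST IV. Ties at the
#' top resolve to CST IV (no single dominant species).
#'
#' @param profile named numeric vector of ASV counts or relative abundances
#'   for one sample (names are ASV ids).
#' @param taxonomy taxonomy table covering the profile's ASVs.
#' @param threshold dominance threshold on relative abundance
#'   (default 0.30).
#' @return one-row data.frame: `cst`, `dominant_taxon`,
#'   `dominant_relabund`, `threshold_used`.
#' @export
assign_cst <- function(profile, taxonomy, threshold = 0.30) {
  if (length(profile) == 0 || sum(profile) == 0) {
    sexome_stop("empty profile", "sexome_zero_sample")
  }
  counts <- matrix(profile, ncol = 1,
                   dimnames = list(names(profile), "s"))
  tax <- taxonomy[match(names(profile), taxonomy$asv_id), , drop = FALSE]
  tax$species_full <- species_label(tax)
  sp <- rowsum(counts, group = tax$species_full)
  rel <- sp[, 1] / sum(sp[, 1])
  top <- max(rel)
  winners <- names(rel)[rel == top]
  dominant <- if (length(winners) == 1) winners else NA_character_
  cst <- "IV"
  if (!is.na(dominant) && dominant %in% cst_species && top >= threshold) {
    cst <- names(cst_species)[match(dominant, cst_species)]
  }
  data.frame(cst = cst,
             dominant_taxon = names(rel)[which.max(rel)],
             dominant_relabund = top,
             threshold_used = threshold)
}

#' Assign CSTs to every female before-intercourse sample
#'
#' @param dataset a `cohort_dataset`.
#' @param threshold dominance threshold, as in [assign_cst()].
#' @return data.frame: `sample_id`, `couple_id`, `cst`, `dominant_taxon`,
#'   `dominant_relabund`, `threshold_used`.
#' @export
assign_cst_cohort <- function(dataset, threshold = 0.30) {
  md <- dataset$metadata
  fb <- md[md$sample_class == "specimen" & md$sex == "female" &
             md$timepoint == "before", ]
  out <- lapply(seq_len(nrow(fb)), function(i) {
    row <- assign_cst(dataset$counts[, fb$sample_id[i]], dataset$taxonomy,
                      threshold)
    cbind(data.frame(sample_id = fb$sample_id[i],
                     couple_id = fb$couple_id[i]), row)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
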