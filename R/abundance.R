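#' Convert a count matrix to relative abundances
#'
#' Divides every column (sample) of an ASV count matrix by its column total,
#' so each sample becomes a composition on the simplex.
#'
#' @param counts numeric matrix, ASVs x samples, or a `cohort_dataset` (its
#'   count matrix is used).
#' @return matrix of proportions with the same dimnames; every column sums
#'   to 1.
#' @export
to_relative_abundance <- function(counts) {
  if (inherits(counts, "cohort_dataset")) counts <- counts$counts
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero) > 0) {
    sexome_stop(
      paste0("sample(s) with zero total reads: ",
             paste(colnames(counts)[zero], collapse = ", ")),
      "sexome_zero_sample")
  }
  sweep(counts, 2, totals, "/")
}

#' Remove ASVs that never exceed a relative-abundance threshold
#'
#' Retains exactly the ASVs whose relative abundance strictly exceeds
#' `threshold` in at least one sample; counts of retained ASVs and the
#' sample set are unchanged. The conventional amplicon-survey setting is
#' 0.001 (0.1%). Samples with zero total reads are ignored when screening
#' (nothing can exceed the threshold there) but are kept in the output.
#'
#' @param dataset a `cohort_dataset` or a count matrix.
#' @param threshold proportion in `[0, 1)`.
#' @return the input with low-abundance ASVs dropped (same class as input).
#' @export
filter_low_abundance <- function(dataset, threshold = 0.001) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold >= 1) {
    sexome_stop("threshold must be a single proportion in [0, 1)",
                "sexome_invalid_threshold")
  }
  counts <- if (inherits(dataset, "cohort_dataset")) dataset$counts else dataset
  nonzero <- colSums(counts) > 0
  rel <- to_relative_abundance(counts[, nonzero, drop = FALSE])
  keep <- rownames(counts)[apply(rel > threshold, 1, any)]
  if (inherits(dataset, "cohort_dataset")) {
    subset_cohort(dataset, asvs = keep)
  } else {
    counts[keep, , drop = FALSE]
  }
}

#' Aggregate ASV counts at a taxonomic rank
#'
#' Sums read counts of all ASVs assigned to the same taxon at the requested
#' rank; ASVs with the sentinel `"unclassified"` at that rank pool under the
#' sentinel. Per-sample read totals are conserved exactly.
#'
#' @param dataset a `cohort_dataset`, or a count matrix if `taxonomy` is
#'   supplied.
#' @param rank one of `"kingdom"`, `"phylum"`, `"class"`, `"order"`,
#'   `"family"`, `"genus"`, `"species"`.
#' @param taxonomy taxonomy data.frame (defaults to the dataset's).
#' @return numeric matrix, taxa-at-rank x samples.
#' @export
aggregate_by_rank <- function(dataset, rank = "genus", taxonomy = NULL) {
  if (inherits(dataset, "cohort_dataset")) {
    counts <- dataset$counts
    taxonomy <- taxonomy %||% dataset$taxonomy
  } else {
    counts <- dataset
    if (is.null(taxonomy)) {
      sexome_stop("taxonomy required when aggregating a bare matrix",
                  "sexome_invalid_taxonomy")
    }
  }
  if (!rank %in% tax_ranks) {
    sexome_stop(paste0("unknown rank: ", rank), "sexome_unknown_rank")
  }
  taxon <- taxonomy[[rank]][match(rownames(counts), taxonomy$asv_id)]
  taxon[is.na(taxon)] <- "unclassified"
  out <- rowsum(counts, group = taxon, reorder = TRUE)
  as.matrix(out)
}

# Species-level label "Genus species"; falls back to the sentinel when the
# species epithet is unassigned.
species_label <- function(taxonomy) {
  ifelse(taxonomy$species == "unclassified", "unclassified",
         ifelse(grepl(" ", taxonomy$species), taxonomy$species,
                paste(taxonomy$genus, taxonomy$species)))
}
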