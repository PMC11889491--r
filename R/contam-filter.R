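#' Prevalence-based contaminant score for one ASV
#'
#' Compares how often an ASV is detected in true specimens versus negative
#' controls (extraction blanks and no-template controls). Reagent and
#' lab-ware contaminants are over-represented in the controls, so the score
#' is the one-sided tail probability that the ASV's prevalence in controls
#' is at least as extreme as observed, computed from the 2x2 presence table:
#' a chi-squared tail in well-filled tables, and the exact hypergeometric
#' tail whenever any expected cell falls below 5 (negative-control panels
#' are small, so the exact branch is the common one). An ASV absent from
#' every control scores 1 by convention.
#'
#' @param specimen_presence logical vector: ASV detected in each specimen.
#' @param control_presence logical vector: ASV detected in each negative
#'   control.
#' @return score in `[0, 1]`; small scores indicate likely contaminants.
#' @seealso [identify_contaminants()]
#' @export
prevalence_score <- function(specimen_presence, control_presence) {
  if (length(specimen_presence) < 1 || length(control_presence) < 1) {
    sexome_stop("need at least one specimen and one negative control",
                "sexome_no_controls")
  }
  a <- sum(specimen_presence)            # specimens with the ASV
  b <- length(specimen_presence) - a
  cc <- sum(control_presence)            # controls with the ASV
  d <- length(control_presence) - cc
  if (cc == 0) return(1)
  n <- a + b + cc + d
  k <- a + cc                            # total samples with the ASV
  expected <- outer(c(a + b, cc + d), c(k, n - k)) / n
  if (any(expected < 5)) {
    # exact tail: P(controls-with-ASV >= cc) under hypergeometric margins
    p <- stats::phyper(cc - 1, k, n - k, cc + d, lower.tail = FALSE)
  } else {
    stat <- n * (a * d - b * cc)^2 /
      ((a + b) * (cc + d) * k * (n - k))
    p2 <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    ctrl_frac <- cc / (cc + d)
    spec_frac <- a / (a + b)
    p <- if (ctrl_frac > spec_frac) p2 / 2 else 1 - p2 / 2
  }
  min(max(p, 0), 1)
}

#' Identify contaminant ASVs by the prevalence method
#'
#' Scores every ASV with [prevalence_score()] against the pooled negative
#' controls and flags those scoring below `threshold` (0.05 in the standard
#' protocol). Mock-community samples take part in neither group.
#'
#' @param dataset a `cohort_dataset` containing at least one negative
#'   control.
#' @param threshold probability threshold below which an ASV is flagged.
#' @param control_classes which sample classes count as negative controls;
#'   by default extraction blanks and no-template controls are pooled.
#' @param min_reads minimum reads for presence (default 1: any read).
#' @return data.frame with columns `asv_id`, `score`, `flagged`,
#'   `n_controls_present`, `n_specimens_present`.
#' @export
identify_contaminants <- function(dataset, threshold = 0.05,
                                  control_classes = c("extraction_blank",
                                                      "no_template_control"),
                                  min_reads = 1) {
  ctrl <- control_ids(dataset, control_classes)
  spec <- specimen_ids(dataset)
  if (length(ctrl) == 0) {
    sexome_stop("no negative-control samples in dataset",
                "sexome_no_controls")
  }
  present <- dataset$counts >= min_reads
  spec_p <- present[, spec, drop = FALSE]
  ctrl_p <- present[, ctrl, drop = FALSE]
  score <- vapply(seq_len(nrow(present)), function(i) {
    prevalence_score(spec_p[i, ], ctrl_p[i, ])
  }, numeric(1))
  data.frame(
    asv_id = rownames(dataset$counts),
    score = score,
    flagged = score < threshold,
    n_controls_present = rowSums(ctrl_p),
    n_specimens_present = rowSums(spec_p),
    row.names = NULL)
}

#' Remove flagged contaminant ASVs from a dataset
#'
#' @param dataset a `cohort_dataset`.
#' @param flags the data.frame returned by [identify_contaminants()], or a
#'   logical vector named by ASV id.
#' @return the dataset without the flagged ASVs; samples are untouched.
#' @export
remove_contaminants <- function(dataset, flags) {
  if (is.data.frame(flags)) {
    flagged <- flags$asv_id[flags$flagged]
  } else {
    flagged <- names(flags)[flags]
  }
  covered <- if (is.data.frame(flags)) flags$asv_id else names(flags)
  uncovered <- setdiff(rownames(dataset$counts), covered)
  if (length(uncovered) > 0) {
    sexome_stop(paste0("flags missing for ASV(s): ",
                       paste(utils::head(uncovered, 5), collapse = ", ")),
                "sexome_crossref_mismatch")
  }
  keep <- setdiff(rownames(dataset$counts), flagged)
  if (length(keep) == 0) {
    warning("all ASVs flagged as contaminants; returning an empty table")
  }
  subset_cohort(dataset, asvs = keep)
}
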