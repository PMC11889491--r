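#' Shannon diversity index
#'
#' \eqn{H = -\sum_i p_i \ln p_i} over taxa with positive counts, with
#' \eqn{p_i} the relative abundance of taxon *i*. Natural logarithm (nats),
#' the convention of the R ecology stack.
#'
#' @param x non-negative count (or abundance) vector with positive total.
#' @return Shannon index in nats.
#' @export
shannon_index <- function(x) {
  if (any(x < 0) || anyNA(x)) {
    sexome_stop("counts must be non-negative", "sexome_invalid_counts")
  }
  total <- sum(x)
  if (total == 0) {
    sexome_stop("all-zero vector has no defined diversity",
                "sexome_zero_sample")
  }
  p <- x[x > 0] / total
  -sum(p * log(p))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Group comparison used for alpha-diversity contrasts: exact by
#' enumeration when both groups have at most 10 observations and there are
#' no ties, the normal approximation with tie and continuity correction
#' otherwise.
#'
#' @param a,b numeric vectors (each non-empty).
#' @return two-sided p-value.
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 1 || length(b) < 1) {
    sexome_stop("both groups must be non-empty", "sexome_empty_group")
  }
  ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- length(a) <= 10 && length(b) <= 10 && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{BC = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}; 0 for identical
#' samples, 1 for samples with disjoint taxon support.
#'
#' @param x,y non-negative vectors of equal length, not both all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(x, y) {
  if (length(x) != length(y)) {
    sexome_stop("vectors must have equal length", "sexome_invalid_counts")
  }
  if (any(x < 0) || any(y < 0)) {
    sexome_stop("counts must be non-negative", "sexome_invalid_counts")
  }
  denom <- sum(x + y)
  if (denom == 0) {
    sexome_stop("both samples are all-zero", "sexome_zero_sample")
  }
  sum(abs(x - y)) / denom
}

#' Bray-Curtis distance matrix over the samples of a count table
#'
#' @param counts matrix (ASVs x samples) or `cohort_dataset`; columns with
#'   zero totals are rejected.
#' @return symmetric sample-by-sample dissimilarity matrix with zero
#'   diagonal.
#' @export
bray_curtis_matrix <- function(counts) {
  if (inherits(counts, "cohort_dataset")) counts <- counts$counts
  if (any(colSums(counts) == 0)) {
    sexome_stop("all-zero sample column(s) in count table",
                "sexome_zero_sample")
  }
  n <- ncol(counts)
  d <- matrix(0, n, n, dimnames = list(colnames(counts), colnames(counts)))
  for (i in seq_len(n - 1)) {
    xi <- counts[, i]
    for (j in seq.int(i + 1, n)) {
      d[i, j] <- d[j, i] <- bray_curtis(xi, counts[, j])
    }
  }
  d
}

validate_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-12 ||
      any(diag(d) != 0) || any(d < 0)) {
    sexome_stop("not a valid distance matrix (square, symmetric, zero diagonal, non-negative)",
                "sexome_invalid_distance")
  }
  d
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering of \eqn{-\tfrac12 D^2} followed by
#' eigendecomposition. Coordinates are eigenvectors scaled by the square
#' root of their (positive) eigenvalues; negative eigenvalues — which arise
#' for non-Euclidean dissimilarities such as Bray-Curtis — are reported but
#' excluded from the coordinates and from the proportion-explained
#' denominator. Axis signs follow the convention that the largest-magnitude
#' loading on each axis is positive.
#'
#' @param d distance matrix (square symmetric, n >= 3).
#' @return object of class `sexome_pcoa`: list with `coordinates`
#'   (samples x positive axes), `eigenvalues` (all, non-increasing) and
#'   `proportion_explained` (per positive axis).
#' @export
pcoa <- function(d) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) sexome_stop("need at least 3 samples", "sexome_invalid_distance")
  a <- -0.5 * d^2
  # double centering: B = (I - J/n) A (I - J/n)
  b <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  eig <- eigen(b, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-9
  pos <- which(eig$values > tol)
  vec <- eig$vectors[, pos, drop = FALSE]
  # deterministic axis orientation
  for (k in seq_along(pos)) {
    j <- which.max(abs(vec[, k]))
    if (vec[j, k] < 0) vec[, k] <- -vec[, k]
  }
  coords <- sweep(vec, 2, sqrt(eig$values[pos]), "*")
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_along(pos))
  structure(
    list(coordinates = coords,
         eigenvalues = eig$values,
         proportion_explained = eig$values[pos] / sum(eig$values[pos])),
    class = "sexome_pcoa")
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Partitions the squared dissimilarities among the levels of a single
#' grouping factor. With \eqn{N} samples in \eqn{a} groups:
#' \deqn{SS_T = \sum_{i<j} d_{ij}^2 / N,\quad
#'       SS_W = \sum_g \sum_{i<j \in g} d_{ij}^2 / n_g,\quad
#'       SS_A = SS_T - SS_W,}
#' pseudo-\eqn{F = (SS_A/(a-1)) / (SS_W/(N-a))} and
#' \eqn{R^2 = SS_A / SS_T}. The p-value uses free permutations of the
#' labels: \eqn{p = (1 + \#\{F^\pi \ge F\}) / (1 + n_{perm})}. With
#' `exact = TRUE` (two groups only) every distinct label assignment is
#' enumerated instead and \eqn{p} is the exact proportion with
#' \eqn{F^\pi \ge F}, the observed assignment included.
#'
#' @param d distance matrix.
#' @param labels grouping vector, one per sample; every group needs >= 2
#'   members.
#' @param n_permutations number of random permutations (ignored when
#'   `exact`).
#' @param seed integer seed for the permutation stream.
#' @param exact enumerate all label assignments (two-group designs).
#' @return object of class `sexome_permanova`: list with `pseudo_F`,
#'   `r_squared`, `p_value`, `n_permutations`, `seed`, `df`.
#' @export
permanova <- function(d, labels, n_permutations = 999, seed = NULL,
                      exact = FALSE) {
  d <- validate_distance_matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  if (length(labels) != n) {
    sexome_stop("labels must cover every sample", "sexome_invalid_labels")
  }
  sizes <- table(labels)
  a <- length(sizes)
  if (a < 2 || any(sizes < 2)) {
    sexome_stop("need >= 2 groups each with >= 2 members",
                "sexome_invalid_labels")
  }
  d2 <- d^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within_for <- function(lab) {
    s <- 0
    for (g in unique(lab)) {
      idx <- which(lab == g)
      dg <- d2[idx, idx, drop = FALSE]
      s <- s + sum(dg[upper.tri(dg)]) / length(idx)
    }
    s
  }
  f_for <- function(lab) {
    ssw <- ss_within_for(lab)
    ((ss_total - ssw) / (a - 1)) / (ssw / (n - a))
  }
  ss_within <- ss_within_for(labels)
  ss_between <- ss_total - ss_within
  degenerate <- ss_within <= ss_total * 1e-12
  f_obs <- if (degenerate) Inf else
    ((ss_between / (a - 1)) / (ss_within / (n - a)))
  if (exact) {
    if (a != 2) {
      sexome_stop("exact enumeration supported for two groups only",
                  "sexome_invalid_labels")
    }
    g1 <- names(sizes)[1]
    combos <- utils::combn(n, sizes[[1]])
    fs <- apply(combos, 2, function(idx) {
      lab <- rep(names(sizes)[2], n)
      lab[idx] <- g1
      f_for(lab)
    })
    p <- mean(fs >= f_obs - 1e-12)
    n_permutations <- ncol(combos) - 1
  } else {
    perm_f <- function() {
      vapply(seq_len(n_permutations),
             function(i) f_for(labels[sample.int(n)]), numeric(1))
    }
    fs <- if (is.null(seed)) perm_f() else with_seed(seed, perm_f())
    if (degenerate) {
      warning("within-group sum of squares is zero; p set to its smallest attainable value")
      p <- 1 / (n_permutations + 1)
    } else {
      p <- (1 + sum(fs >= f_obs - 1e-12)) / (1 + n_permutations)
    }
  }
  structure(
    list(pseudo_F = f_obs,
         r_squared = ss_between / ss_total,
         p_value = p,
         n_permutations = n_permutations,
         seed = seed,
         df = c(between = a - 1, within = n - a)),
    class = "sexome_permanova")
}

#' @export
print.sexome_permanova <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA (one factor): pseudo-F = %.4g, R2 = %.4f, p = %.4g (%d permutations)\n",
    x$pseudo_F, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' Per-sample alpha diversity with group comparisons
#'
#' Computes observed ASV richness and Shannon diversity for every specimen,
#' labelled by a metadata grouping field, plus a two-sided Wilcoxon
#' rank-sum p-value for every pair of group levels (no comparisons when the
#' grouping has a single level).
#'
#' @param dataset a `cohort_dataset`.
#' @param grouping name of a metadata column (e.g. `"sex"`).
#' @return list with `samples` (data.frame: sample_id, group, richness,
#'   shannon) and `comparisons` (data.frame: group1, group2, p_value).
#' @export
alpha_table <- function(dataset, grouping = "sex") {
  md <- dataset$metadata
  if (!grouping %in% names(md)) {
    sexome_stop(paste0("unknown grouping field: ", grouping),
                "sexome_unknown_field")
  }
  spec <- specimen_ids(dataset)
  counts <- dataset$counts[, spec, drop = FALSE]
  group <- md[[grouping]][match(spec, md$sample_id)]
  samples <- data.frame(
    sample_id = spec,
    group = group,
    richness = colSums(counts > 0),
    shannon = apply(counts, 2, shannon_index),
    row.names = NULL)
  levels_ <- sort(unique(as.character(group)))
  comparisons <- data.frame(group1 = character(0), group2 = character(0),
                            p_value = numeric(0))
  if (length(levels_) >= 2) {
    pairs <- utils::combn(levels_, 2)
    comparisons <- data.frame(
      group1 = pairs[1, ], group2 = pairs[2, ],
      p_value = apply(pairs, 2, function(pr) {
        rank_sum_test(samples$shannon[group == pr[1]],
                      samples$shannon[group == pr[2]])
      }))
  }
  list(samples = samples, comparisons = comparisons, grouping = grouping)
}
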