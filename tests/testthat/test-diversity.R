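test_that("Shannon index matches closed forms and the reference implementation", {
  expect_equal(shannon_index(c(10, 0, 0)), 0)
  for (k in c(2, 4, 7, 10)) {
    expect_equal(shannon_index(rep(1, k)), log(k), tolerance = 1e-15)
  }
  # direct summation oracle
  x <- c(5, 3, 2)
  p <- x / sum(x)
  expect_equal(shannon_index(x), -sum(p * log(p)), tolerance = 1e-12)
  skip_if_not_installed("vegan")
  set.seed(3)
  m <- matrix(rpois(50, 6) + 1, 10, 5)
  expect_equal(apply(m, 2, shannon_index),
               vegan::diversity(t(m), "shannon"),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(shannon_index(c(0, 0)), class = "sexome_zero_sample")
})

test_that("rank-sum test is exact on small tie-free groups and approximate otherwise", {
  expect_equal(rank_sum_test(c(3, 1, 7), c(3, 1, 7)), 1)
  # most extreme of the C(4,2)=6 assignments, doubled for two sides
  expect_equal(rank_sum_test(c(1, 2), c(3, 4)), 1 / 3, tolerance = 1e-12)

  # large tied groups: compare with a permutation oracle of the rank-sum
  # statistic (two-sided by statistic distance from its null mean)
  set.seed(9)
  a <- sample(rep(1:6, 2), 12)
  b <- sample(rep(2:7, 2), 12)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_along(a)])
  null_mean <- length(a) * (length(a) + length(b) + 1) / 2
  perm <- replicate(40000, {
    idx <- sample(24, 12)
    sum(rank(c(a, b))[idx])
  })
  p_oracle <- mean(abs(perm - null_mean) >= abs(w_obs - null_mean) - 1e-9)
  expect_lt(abs(rank_sum_test(a, b) - p_oracle), 0.01)
  expect_error(rank_sum_test(numeric(0), 1), class = "sexome_empty_group")
})

test_that("Bray-Curtis matches its formula, bounds and the vegan oracle", {
  expect_equal(bray_curtis(c(2, 1), c(2, 1)), 0)
  expect_equal(bray_curtis(c(1, 0, 2), c(0, 3, 0)), 1)
  expect_equal(bray_curtis(c(1, 0, 1), c(0, 1, 1)), 0.5)
  set.seed(21)
  for (i in 1:200) {
    x <- rpois(15, 4); y <- rpois(15, 4)
    if (sum(x + y) == 0) next
    bc <- bray_curtis(x, y)
    expect_equal(bc, sum(abs(x - y)) / sum(x + y), tolerance = 1e-12)
    expect_equal(bc, bray_curtis(y, x))
    expect_true(bc >= 0 && bc <= 1)
    expect_equal(bc == 0, all(x == y))
  }
  skip_if_not_installed("vegan")
  m <- matrix(rpois(60, 10), 12, 5, dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(bray_curtis_matrix(m),
               as.matrix(vegan::vegdist(t(m), "bray")),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), class = "sexome_zero_sample")
})

test_that("PCoA recovers planted geometry and normalises explained variance", {
  # equilateral triangle: two equal eigenvalues, third ~ 0
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  p3 <- pcoa(d3)
  expect_equal(p3$eigenvalues[1], p3$eigenvalues[2], tolerance = 1e-10)
  expect_lt(abs(p3$eigenvalues[3]), 1e-10)

  # planted 2-D Euclidean configuration is reproduced exactly
  set.seed(14)
  pts <- matrix(rnorm(10), 5, 2)
  de <- as.matrix(dist(pts))
  dimnames(de) <- list(paste0("s", 1:5), paste0("s", 1:5))
  pe <- pcoa(de)
  expect_lt(max(abs(as.matrix(dist(pe$coordinates[, 1:2])) - de)), 1e-8)

  # Bray-Curtis table: proportions over positive axes sum to 1
  m <- matrix(rpois(200, 7), 20, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  pb <- pcoa(bray_curtis_matrix(m))
  expect_equal(sum(pb$proportion_explained), 1, tolerance = 1e-9)
  expect_true(all(diff(pb$eigenvalues) <= 1e-12))

  skip_if_not_installed("ape")
  pa <- ape::pcoa(stats::as.dist(bray_curtis_matrix(m)))
  n_pos <- ncol(pb$coordinates)
  expect_equal(pb$eigenvalues[1:n_pos],
               pa$values$Eigenvalues[1:n_pos], tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(as.matrix(dist(pb$coordinates[, 1:3])),
               as.matrix(dist(pa$vectors[, 1:3])), tolerance = 1e-8,
               ignore_attr = TRUE)

  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(pcoa(bad), class = "sexome_invalid_distance")
})

test_that("PERMANOVA partitions variance correctly and is reproducible", {
  # duplicated identical groups: zero between-group signal
  m <- matrix(rpois(30, 9), 10, 3)
  mm <- cbind(m, m)
  colnames(mm) <- paste0("s", 1:6)
  d <- bray_curtis_matrix(mm)
  res <- permanova(d, rep(c("A", "B"), each = 3), n_permutations = 99,
                   seed = 1)
  expect_equal(res$r_squared, 0, tolerance = 1e-12)

  # seeded reproducibility, bit for bit
  set.seed(30)
  m2 <- matrix(rpois(120, 8), 12, 10, dimnames = list(NULL, paste0("s", 1:10)))
  d2 <- bray_curtis_matrix(m2)
  lab <- rep(c("x", "y"), each = 5)
  p1 <- permanova(d2, lab, n_permutations = 499, seed = 77)
  p2 <- permanova(d2, lab, n_permutations = 499, seed = 77)
  expect_identical(p1$p_value, p2$p_value)
  expect_equal((p1$p_value * (499 + 1)) %% 1, 0, tolerance = 1e-9)

  skip_if_not_installed("vegan")
  ad <- vegan::adonis2(stats::as.dist(d2) ~ lab, permutations = 499)
  expect_equal(p1$pseudo_F, ad$F[1], tolerance = 1e-10)
  expect_equal(p1$r_squared, ad$R2[1], tolerance = 1e-10)

  expect_error(permanova(d2, rep(c("x", "y", "z"), c(5, 4, 1))),
               class = "sexome_invalid_labels")
})

test_that("exact PERMANOVA enumeration equals a hand-rolled oracle on 6 samples", {
  set.seed(41)
  m <- matrix(rpois(48, 6), 8, 6, dimnames = list(NULL, paste0("s", 1:6)))
  d <- bray_curtis_matrix(m)
  lab <- rep(c("g1", "g2"), each = 3)
  got <- permanova(d, lab, exact = TRUE)

  # oracle: recompute F over all 20 subsets directly from the definition
  d2 <- d^2
  n <- 6
  ss_tot <- sum(d2[upper.tri(d2)]) / n
  f_of <- function(idx) {
    g1 <- idx; g2 <- setdiff(1:6, idx)
    ssw <- sum(d2[g1, g1][upper.tri(d2[g1, g1])]) / 3 +
      sum(d2[g2, g2][upper.tri(d2[g2, g2])]) / 3
    ((ss_tot - ssw) / 1) / (ssw / 4)
  }
  fs <- apply(utils::combn(6, 3), 2, f_of)
  f_obs <- f_of(1:3)
  expect_equal(got$pseudo_F, f_obs, tolerance = 1e-12)
  expect_equal(got$p_value, mean(fs >= f_obs - 1e-12), tolerance = 1e-12)
})

test_that("alpha table reports richness, Shannon and pairwise group tests", {
  sim <- simulate_cohort(simulation_config(seed = 2, n_couples = 3,
                                           read_depth_mean = 2000))
  at <- alpha_table(sim$dataset, "sex")
  expect_equal(nrow(at$samples), 12)
  one <- at$samples$sample_id[1]
  expect_equal(at$samples$richness[1],
               sum(sim$dataset$counts[, one] > 0))
  expect_equal(nrow(at$comparisons), 1)
  expect_true(at$comparisons$p_value >= 0 && at$comparisons$p_value <= 1)

  # constant grouping: no comparisons
  at2 <- alpha_table(sim$dataset, "sample_class")
  expect_equal(nrow(at2$comparisons), 0)
  expect_error(alpha_table(sim$dataset, "nope"),
               class = "sexome_unknown_field")
})
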