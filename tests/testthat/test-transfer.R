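# One couple with prescribed support sets; counts are 10 reads per present
# ASV so presence thresholds are unambiguous.
couple_from_supports <- function(fb, fa, mb, ma,
                                 asvs = sprintf("t%02d", 1:12)) {
  col <- function(sup) { x <- integer(length(asvs)); x[match(sup, asvs)] <- 10L
    stats::setNames(x, asvs) }
  build_dataset(
    list(K_f_b = col(fb), K_f_a = col(fa), K_m_b = col(mb), K_m_a = col(ma)),
    rbind(specimen_row("K_f_b", "KF", "K", "female", "before"),
          specimen_row("K_f_a", "KF", "K", "female", "after"),
          specimen_row("K_m_b", "KM", "K", "male", "before"),
          specimen_row("K_m_a", "KM", "K", "male", "after")),
    simple_taxonomy(asvs))
}

test_that("baseline community is the before/after support intersection", {
  ds <- couple_from_supports(fb = c("t01", "t02", "t03"),
                             fa = c("t02", "t03", "t04"),
                             mb = c("t05", "t06"), ma = c("t07"))
  b <- baseline_communities(ds)
  expect_setequal(b$asv_id[b$participant_id == "KF"], c("t02", "t03"))
  expect_equal(sum(b$participant_id == "KM"), 0)  # disjoint -> empty

  # a participant without an after sample is rejected
  ds2 <- ds
  keep <- ds2$metadata$sample_id != "K_m_a"
  broken <- cohort_dataset(ds2$counts[, keep, drop = FALSE], ds2$taxonomy,
                           ds2$metadata[keep, ])
  expect_error(baseline_communities(broken),
               class = "sexome_missing_timepoint")
})

test_that("cohort uniqueness flags match brute-force occurrence counting", {
  set.seed(51)
  for (rep in 1:10) {
    ds <- random_mini_cohort(n_couples = 3, n_asvs = 18)
    flagged <- cohort_unique_flags(baseline_communities(ds))
    # brute force: recompute baselines from raw supports and count
    md <- ds$metadata
    sup <- lapply(stats::setNames(md$sample_id, md$sample_id),
                  function(s) support_of(ds, s))
    base <- list()
    for (p in unique(md$participant_id)) {
      ids <- md$sample_id[md$participant_id == p]
      tp <- md$timepoint[match(ids, md$sample_id)]
      base[[p]] <- intersect(sup[[ids[tp == "before"]]],
                             sup[[ids[tp == "after"]]])
    }
    occurrences <- table(unlist(base))
    for (i in seq_len(nrow(flagged))) {
      expect_identical(
        flagged$cohort_unique[i],
        unname(occurrences[flagged$asv_id[i]] == 1),
        label = paste("row", i, "rep", rep))
    }
    expect_setequal(
      paste(flagged$participant_id, flagged$asv_id),
      unlist(lapply(names(base), function(p) {
        if (length(base[[p]]) == 0) NULL else paste(p, base[[p]])
      })))
  }
})

test_that("after-sample ASVs partition into retained/transferred/introduced", {
  ds <- couple_from_supports(
    fb = c("t01", "t02"), fa = c("t01", "t05", "t09"),
    mb = c("t05", "t06"), ma = c("t02", "t05", "t09"))
  cls <- classify_after_asvs(ds, "K")
  male <- cls[cls$recipient_sex == "male", ]
  expect_equal(male$category[male$asv_id == "t05"], "retained")
  expect_equal(male$category[male$asv_id == "t02"], "transferred")
  expect_equal(male$category[male$asv_id == "t09"], "introduced")
  expect_equal(male$category[male$asv_id == "t06"], "lost")
  female <- cls[cls$recipient_sex == "female", ]
  # t09 absent from both before samples appears in both partners
  expect_equal(female$category[female$asv_id == "t09"], "introduced")
  expect_equal(female$category[female$asv_id == "t05"], "transferred")

  # transferred calls carry donor/recipient relative abundances
  tr <- male[male$asv_id == "t02", ]
  expect_equal(tr$donor_before_abundance, 0.5)  # t02 is 1 of 2 in fb
  expect_equal(tr$recipient_after_abundance, 1 / 3)
})

test_that("classification equals brute-force set recomputation on random couples", {
  set.seed(52)
  for (rep in 1:20) {
    ds <- random_mini_cohort(n_couples = 1, n_asvs = 15)
    cls <- classify_after_asvs(ds, "K1")
    sup <- lapply(stats::setNames(colnames(ds$counts), colnames(ds$counts)),
                  function(s) support_of(ds, s))
    for (sex in c("male", "female")) {
      own_b <- sup[[if (sex == "male") "K1_m_before" else "K1_f_before"]]
      own_a <- sup[[if (sex == "male") "K1_m_after" else "K1_f_after"]]
      par_b <- sup[[if (sex == "male") "K1_f_before" else "K1_m_before"]]
      want <- ifelse(own_a %in% own_b, "retained",
                     ifelse(own_a %in% par_b, "transferred", "introduced"))
      side <- cls[cls$recipient_sex == sex & cls$category != "lost", ]
      expect_identical(
        stats::setNames(side$category, side$asv_id)[own_a],
        stats::setNames(want, own_a))
      # partition property
      expect_equal(nrow(side), length(own_a))
      expect_setequal(side$asv_id[side$category == "retained"],
                      intersect(own_a, own_b))
    }
  }
})

test_that("couple summary reconstructs percentages as 100*unique/total to one decimal", {
  set.seed(53)
  for (rep in 1:5) {
    ds <- random_mini_cohort(n_couples = 3, n_asvs = 20)
    ts <- transfer_summary(ds)
    s <- ts$summary
    for (stub in c("female_baseline", "male_baseline", "f2m_transfer",
                   "m2f_transfer")) {
      tot <- s[[paste0(stub, "_total")]]
      unq <- s[[paste0(stub, "_unique")]]
      pc <- s[[paste0(stub, "_pct")]]
      expect_true(all(unq >= 0 & unq <= tot))
      want <- ifelse(tot == 0, NA_real_,
                     trunc(100 * unq / tot * 10 + 0.5) / 10)
      expect_equal(pc, want, label = stub)
    }
  }
})

test_that("relabeling sexes while swapping directions leaves counts invariant", {
  set.seed(54)
  ds <- random_mini_cohort(n_couples = 2, n_asvs = 16)
  md2 <- ds$metadata
  md2$sex <- ifelse(md2$sex == "male", "female", "male")
  ds2 <- cohort_dataset(ds$counts, ds$taxonomy, md2)
  s1 <- transfer_summary(ds)$summary
  s2 <- transfer_summary(ds2)$summary
  expect_equal(s1$female_baseline_total, s2$male_baseline_total)
  expect_equal(s1$female_baseline_unique, s2$male_baseline_unique)
  expect_equal(s1$f2m_transfer_total, s2$m2f_transfer_total)
  expect_equal(s1$f2m_transfer_unique, s2$m2f_transfer_unique)
  expect_equal(s1$m2f_transfer_total, s2$f2m_transfer_total)
})

test_that("contributor rule requires opposite-signed abundance changes", {
  m <- rbind(
    Finegoldia = c(female_before = 0.01, female_after = 0.10,
                   male_before = 0.20, male_after = 0.05),
    Lactobacillus = c(0.50, 0.30, 0.02, 0.20),
    Prevotella = c(0.10, 0.20, 0.10, 0.30),
    Stable = c(0.39, 0.40, 0.68, 0.45))
  calls <- contributor_genera(m, delta = 0.005)
  expect_equal(calls$direction[calls$genus == "Finegoldia"],
               "male_contributor")
  expect_equal(calls$direction[calls$genus == "Lactobacillus"],
               "female_contributor")
  expect_equal(calls$direction[calls$genus == "Prevotella"], "none")
  # below-tolerance changes do not qualify
  tiny <- rbind(G = c(0.100, 0.102, 0.100, 0.098))
  colnames(tiny) <- colnames(m)
  expect_equal(contributor_genera(tiny, delta = 0.005)$direction, "none")
  expect_equal(contributor_genera(tiny, delta = 0)$direction,
               "male_contributor")
})

test_that("recovery report is null-safe and monotone in mixing", {
  cfgs <- function(m) lapply(1:4, function(i) {
    couple_config(sprintf("C%02d", i), cst = c("I", "III", "IV", "II")[i],
                  transfer_fm = m, transfer_mf = m)
  })
  base_cfg <- simulation_config(seed = 19, n_couples = 4,
                                read_depth_mean = 8292,
                                contamination = FALSE)
  # zero mixing: no planted transfers and no transfer calls
  sim0 <- simulate_cohort(base_cfg, cfgs(0))
  ts0 <- transfer_summary(sim0$dataset)
  rep0 <- transfer_recovery_report(ts0$classification, sim0$ground_truth)
  expect_equal(nrow(sim0$ground_truth$planted_transfers), 0)
  expect_equal(nrow(rep0$false_positives) +
                 sum(ts0$classification$category == "transferred") -
                 nrow(rep0$explainable), 0)

  # graded mixing: recovered counts non-decreasing
  rec <- vapply(c(0.05, 0.15, 0.35), function(m) {
    sim <- simulate_cohort(base_cfg, cfgs(m))
    ts <- transfer_summary(sim$dataset)
    transfer_recovery_report(ts$classification, sim$ground_truth)$n_recovered
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
})
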