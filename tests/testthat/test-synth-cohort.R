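test_that("simulation is deterministic given configuration and seed", {
  cfg <- simulation_config(seed = 7, n_couples = 3, read_depth_mean = 2000)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$dataset$counts, s2$dataset$counts)
  expect_identical(s1$dataset$metadata, s2$dataset$metadata)
  expect_identical(s1$ground_truth$planted_transfers,
                   s2$ground_truth$planted_transfers)
  s3 <- simulate_cohort(simulation_config(seed = 8, n_couples = 3,
                                          read_depth_mean = 2000))
  expect_false(identical(s1$dataset$counts, s3$dataset$counts))
})

test_that("cohort layout matches the study design it emulates", {
  sim <- simulate_cohort(simulation_config(seed = 1, n_couples = 12,
                                           read_depth_mean = 2000))
  md <- sim$dataset$metadata
  expect_equal(sum(md$sample_class == "specimen"), 48)
  expect_equal(sum(md$sample_class == "extraction_blank"), 3)
  expect_equal(sum(md$sample_class == "no_template_control"), 2)
  expect_equal(sum(md$sample_class == "mock"), 1)
  spec <- md[md$sample_class == "specimen", ]
  expect_equal(length(unique(spec$couple_id)), 12)
  expect_true(all(table(spec$couple_id) == 4))
  # read depths are overdispersed around the configured mean
  depths <- colSums(sim$dataset$counts[, spec$sample_id])
  expect_gt(mean(depths), 2000 * 0.8)
  expect_lt(mean(depths), 2000 * 1.2)
})

test_that("no-transfer null and total-replacement limits behave as designed", {
  cfgs <- function(fm, mf) lapply(1:3, function(i) {
    couple_config(sprintf("C%02d", i), cst = c("I", "IV", "III")[i],
                  transfer_fm = fm, transfer_mf = mf, n_introduced = 0)
  })
  base <- function(seed) simulation_config(seed = seed, n_couples = 3,
                                           read_depth_mean = 5e4,
                                           contamination = FALSE,
                                           include_mock = FALSE)
  # null: at high depth, after supports never exceed own before supports
  sim0 <- simulate_cohort(base(31), cfgs(0, 0))
  md <- sim0$dataset$metadata
  for (p in unique(md$participant_id[md$sample_class == "specimen"])) {
    ids <- md$sample_id[md$participant_id == p & !is.na(md$participant_id)]
    tp <- md$timepoint[match(ids, md$sample_id)]
    expect_true(all(support_of(sim0$dataset, ids[tp == "after"]) %in%
                      support_of(sim0$dataset, ids[tp == "before"])))
  }
  # total replacement: male after equals female before up to sampling noise
  sim1 <- simulate_cohort(base(32), cfgs(1, 0))
  for (i in 1:3) {
    cid <- sprintf("C%02d", i)
    fb <- sim1$dataset$counts[, paste0(cid, "_F_before")]
    ma <- sim1$dataset$counts[, paste0(cid, "_M_after")]
    expect_lt(bray_curtis(fb / sum(fb), ma / sum(ma)), 0.05)
  }
})

test_that("controls carry only contaminants and the mock only its eight taxa", {
  sim <- simulate_cohort(simulation_config(seed = 5, n_couples = 2,
                                           read_depth_mean = 2000))
  ds <- sim$dataset
  contam <- sim$ground_truth$contaminants
  for (b in c("BLANK1", "BLANK2", "BLANK3", "NTC1", "NTC2")) {
    expect_true(all(support_of(ds, b) %in% contam), label = b)
  }
  mock_sup <- support_of(ds, "MOCK1")
  mock_species <- ds$taxonomy$species[match(mock_sup, ds$taxonomy$asv_id)]
  expect_true(all(mock_species %in% names(mock_observed_profile())))
  expect_equal(sum(ds$counts[, "MOCK1"]), 27993)
})

test_that("planted transfers appear at the closed-form detection frequency", {
  hits <- numeric(0)
  preds <- numeric(0)
  for (seed in 1:5) {
    sim <- simulate_cohort(
      simulation_config(seed = seed, n_couples = 12,
                        read_depth_mean = 8292, contamination = FALSE))
    pt <- sim$ground_truth$planted_transfers
    recip <- ifelse(pt$direction == "female_to_male",
                    paste0(pt$couple_id, "_M_after"),
                    paste0(pt$couple_id, "_F_after"))
    donor_b <- ifelse(pt$direction == "female_to_male",
                      paste0(pt$couple_id, "_F_before"),
                      paste0(pt$couple_id, "_M_before"))
    seen <- vapply(seq_len(nrow(pt)), function(i) {
      sim$dataset$counts[pt$asv_id[i], recip[i]] > 0 &&
        sim$dataset$counts[pt$asv_id[i], donor_b[i]] > 0
    }, logical(1))
    hits <- c(hits, seen)
    preds <- c(preds, pt$detection_probability)
  }
  # Monte-Carlo bound on the mean detection frequency
  se <- sqrt(sum(preds * (1 - preds))) / length(preds)
  expect_lt(abs(mean(hits) - mean(preds)), 4 * se + 0.005)
})

test_that("mock fixture and its evaluator agree with binomial expectations", {
  fx <- make_mock_fixture(depth = 20000)
  expect_equal(sum(fx$column), 20000)
  expect_equal(fx$expected$proportion, rep(0.125, 8))

  # observed protocol profile is reproduced at large depth
  prof <- mock_observed_profile()
  set.seed(71)
  fx2 <- make_mock_fixture(prof, depth = 2e5)
  expect_lt(max(abs(fx2$column / sum(fx2$column) - prof / sum(prof))),
            0.005)
  expect_error(make_mock_fixture(depth = 0), class = "sexome_invalid_config")

  # evaluator: identity, missing taxon, multinomial deviation bound
  ev0 <- evaluate_mock(stats::setNames(prof * 1000, names(prof)), prof)
  expect_equal(ev0$max_deviation, 0, tolerance = 1e-12)
  obs_missing <- prof[-1] * 1000
  ev1 <- evaluate_mock(obs_missing, prof)
  miss <- ev1$per_taxon[ev1$per_taxon$taxon == names(prof)[1], ]
  expect_equal(miss$observed, 0)
  expect_equal(miss$abs_deviation, unname(prof[1] / sum(prof)),
               tolerance = 1e-3)
  set.seed(72)
  fx3 <- make_mock_fixture(prof, depth = 28000)
  ev3 <- evaluate_mock(fx3$column, prof)
  expect_lt(ev3$max_deviation, 0.01)
  expect_equal(ev3$off_target, 0)
})

test_that("penile communities are richer and more diverse than vaginal ones", {
  shannon_means <- sapply(1:3, function(seed) {
    sim <- simulate_cohort(simulation_config(seed = seed, n_couples = 10,
                                             read_depth_mean = 4000))
    at <- alpha_table(sim$dataset, "sex")
    before <- at$samples[grepl("before",  at$samples$sample_id), ]
    tapply(before$shannon, before$group, mean)
  })
  expect_true(all(shannon_means["male", ] > shannon_means["female", ]))
})

test_that("simulation writes the cohort dialect plus ground truth and config echo", {
  sim <- simulate_cohort(simulation_config(seed = 3, n_couples = 2,
                                           read_depth_mean = 1000))
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  expect_true(all(file.exists(paths)))
  back <- read_cohort(paths["counts"], paths["taxonomy"], paths["metadata"])
  expect_identical(back$counts, sim$dataset$counts)
  gt <- utils::read.table(paths["ground_truth"], sep = "\t", header = TRUE)
  expect_equal(nrow(gt), nrow(sim$ground_truth$planted_transfers))
})
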