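#' Simulation configuration for a synthetic cohort
#'
#' Defaults mirror the design this simulator emulates: 12 couples sampled
#' before and after intercourse (2 partners x 2 timepoints), mean read
#' depth 8,292 with negative-binomial overdispersion, three extraction
#' blanks, two no-template controls and one 8-species mock community, with
#' low-level reagent contamination carried into specimens.
#'
#' @param n_couples number of couples (>= 1).
#' @param read_depth_mean mean reads per specimen.
#' @param read_depth_dispersion negative-binomial size parameter for the
#'   per-sample depth draw (larger = less overdispersed).
#' @param n_extraction_blanks,n_ntc numbers of extraction blanks and
#'   no-template controls.
#' @param include_mock include one mock-community sample.
#' @param mock_depth reads for the mock sample.
#' @param contamination plant reagent contaminants into specimens and
#'   controls (disable for clean-room validation runs).
#' @param contaminant_specimen_prob,contaminant_control_prob per-taxon
#'   carryover probability into a specimen / presence probability in an
#'   extraction blank.
#' @param contaminant_relabund relative abundance at which a carried-over
#'   contaminant enters a specimen.
#' @param generate_sequences attach synthetic nucleotide sequences to the
#'   ASVs.
#' @param seed integer seed; the whole cohort is deterministic given the
#'   configuration and this seed.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(n_couples = 12,
                              read_depth_mean = 8292,
                              read_depth_dispersion = 30,
                              n_extraction_blanks = 3,
                              n_ntc = 2,
                              include_mock = TRUE,
                              mock_depth = 27993,
                              contamination = TRUE,
                              contaminant_specimen_prob = 0.15,
                              contaminant_control_prob = 0.9,
                              contaminant_relabund = 0.005,
                              generate_sequences = FALSE,
                              seed = 1) {
  if (n_couples < 1) sexome_stop("n_couples must be >= 1",
                                 "sexome_invalid_config")
  if (read_depth_mean <= 0) sexome_stop("read depth mean must be positive",
                                        "sexome_invalid_config")
  structure(as.list(environment()), class = "simulation_config")
}

#' Per-couple simulation configuration
#'
#' @param couple_id couple label.
#' @param cst planted community state type of the female partner.
#' @param transfer_fm,transfer_mf mixing proportion of the partner's before
#'   community into the male / female after community, in `[0, 1]`.
#' @param n_introduced number of environmental taxa introduced into the
#'   couple's after samples.
#' @param condom condom used; scales the mixing proportions by
#'   `condom_factor_fm` / `condom_factor_mf` (transfer persists mostly
#'   female-to-male under barrier protection).
#' @param condom_factor_fm,condom_factor_mf scaling applied when `condom`.
#' @return list of class `couple_config`.
#' @export
couple_config <- function(couple_id, cst = "III", transfer_fm = 0.1,
                          transfer_mf = 0.1, n_introduced = 0,
                          condom = FALSE, condom_factor_fm = 0.3,
                          condom_factor_mf = 0.05) {
  if (!cst %in% c("I", "II", "III", "IV", "V")) {
    sexome_stop("cst must be one of I, II, III, IV, V",
                "sexome_invalid_config")
  }
  if (transfer_fm < 0 || transfer_fm > 1 || transfer_mf < 0 ||
      transfer_mf > 1) {
    sexome_stop("mixing proportions must lie in [0, 1]",
                "sexome_invalid_config")
  }
  structure(as.list(environment()), class = "couple_config")
}

#' Default per-couple configurations
#'
#' Draws, from the current RNG stream, a community state type per couple
#' (CST prevalences 0.30/0.10/0.30/0.25/0.05 for I/II/III/IV/V), mixing
#' proportions uniform in `[0.05, 0.2]` in both directions, and 0-3
#' introduced environmental taxa; no condoms.
#'
#' @param n_couples number of couples.
#' @return list of [couple_config()] objects.
#' @export
default_couple_configs <- function(n_couples) {
  csts <- sample(c("I", "II", "III", "IV", "V"), n_couples, replace = TRUE,
                 prob = c(0.30, 0.10, 0.30, 0.25, 0.05))
  lapply(seq_len(n_couples), function(i) {
    couple_config(
      couple_id = sprintf("C%02d", i),
      cst = csts[i],
      transfer_fm = stats::runif(1, 0.05, 0.2),
      transfer_mf = stats::runif(1, 0.05, 0.2),
      n_introduced = sample(0:3, 1))
  })
}

# Draw one community composition over the full taxon list. Returns a
# proportion vector indexed like `pool$asv_id`.
draw_community <- function(pool, niche_set, k_range, dominant_species = NULL,
                           dominance_range = c(0.70, 0.95),
                           exclude_species = character(0)) {
  candidates <- pool[pool$niche %in% niche_set &
                       !pool$species %in% c(dominant_species,
                                            exclude_species), ]
  k <- sample(seq(k_range[1], k_range[2]), 1)
  k <- min(k, nrow(candidates))
  chosen <- candidates[sample(nrow(candidates), k), ]
  w <- stats::rlnorm(k, meanlog = chosen$meanlog, sdlog = chosen$sdlog)
  comp <- stats::setNames(numeric(nrow(pool)), pool$asv_id)
  if (!is.null(dominant_species)) {
    d <- stats::runif(1, dominance_range[1], dominance_range[2])
    comp[pool$asv_id[pool$species == dominant_species]] <- d
    comp[chosen$asv_id] <- (1 - d) * w / sum(w)
  } else {
    comp[chosen$asv_id] <- w / sum(w)
  }
  comp
}

# Mix `extra` mass into `comp` at total proportion sum(extra): comp is
# rescaled to keep the simplex.
blend_in <- function(comp, extra) {
  s <- sum(extra)
  comp <- comp * (1 - s)
  comp[names(extra)] <- comp[names(extra)] + extra
  comp
}

#' Simulate a couple-paired before/after cohort with ground truth
#'
#' Generates, deterministically for a given configuration and seed, a full
#' synthetic cohort: CST-structured female vaginal communities (the
#' designated *Lactobacillus* drawn to 70-95% relative abundance for CSTs
#' I/II/III/V; diverse anaerobes and no CST-defining species for IV),
#' richer penile-skin communities, after-intercourse compositions formed by
#' mixing the partner's before community at the configured proportion plus
#' introduced environmental taxa, multinomial read sampling at
#' negative-binomial depths, contaminant carryover, extraction blanks,
#' no-template controls and a mock community — together with the ground
#' truth needed to validate every downstream stage.
#'
#' Planted transfers are recorded with their closed-form detection
#' probability: the probability that the donor's before sample shows the
#' taxon and the recipient's after sample captures at least one read of it
#' at the realized depths.
#'
#' @param config a [simulation_config()].
#' @param couple_configs list of [couple_config()]; defaults to
#'   [default_couple_configs()] drawn inside the seeded stream.
#' @return list with `dataset` (a [cohort_dataset()]) and `ground_truth`
#'   (class `ground_truth`: `planted_transfers`, `contaminants`,
#'   `cst_by_female`, `mixing`, `true_supports`, participant maps).
#' @export
simulate_cohort <- function(config = simulation_config(),
                            couple_configs = NULL) {
  with_seed(config$seed, simulate_cohort_impl(config, couple_configs))
}

simulate_cohort_impl <- function(config, couple_configs) {
  if (is.null(couple_configs)) {
    couple_configs <- default_couple_configs(config$n_couples)
  }
  if (length(couple_configs) != config$n_couples) {
    sexome_stop("couple_configs length must equal n_couples",
                "sexome_invalid_config")
  }
  pool <- default_niche_pool()
  # personal ASV blocks: a few participant-specific sequence variants of
  # niche-appropriate species per participant, mirroring the strain-level
  # individuality that makes cohort-unique ASVs possible in real data
  personal_species <- list()
  for (cc in couple_configs) {
    for (sx in c("F", "M")) {
      pid <- paste0(cc$couple_id, sx)
      src <- if (sx == "F") c("vaginal", "shared") else
        c("penile_skin", "shared")
      n_p <- sample(2:6, 1)
      personal_species[[pid]] <- sample(pool$species[pool$niche %in% src],
                                        n_p, replace = TRUE)
    }
  }
  taxa <- pool[, c("asv_id", "species")]
  personal_ids <- list()
  for (pid in names(personal_species)) {
    ids <- sprintf("ASV%03d", nrow(taxa) + seq_along(personal_species[[pid]]))
    taxa <- rbind(taxa, data.frame(asv_id = ids,
                                   species = personal_species[[pid]]))
    personal_ids[[pid]] <- ids
  }
  if (config$include_mock) {
    mock_ids <- sprintf("ASV%03d", nrow(taxa) + seq_along(mock_taxa))
    taxa <- rbind(taxa, data.frame(asv_id = mock_ids, species = mock_taxa))
  }
  n_taxa <- nrow(taxa)
  contam_ids <- pool$asv_id[pool$niche == "contaminant"]
  env_pool <- pool[pool$niche == "environmental", ]

  counts <- matrix(0L, n_taxa, 0, dimnames = list(taxa$asv_id, NULL))
  metadata <- list()
  planted <- list()
  supports <- list()
  mixing <- list()
  female_by_couple <- character(0)
  male_by_couple <- character(0)
  cst_by_female <- character(0)

  # lift a pool-level composition onto the full taxon list, then give the
  # participant's personal ASVs a modest share of the community
  expand_comp <- function(x) {
    full <- stats::setNames(numeric(n_taxa), taxa$asv_id)
    full[names(x)] <- x
    full
  }
  add_personal <- function(comp, pid) {
    ids <- personal_ids[[pid]]
    if (is.null(ids) || length(ids) == 0) return(comp)
    mass <- stats::runif(1, 0.05, 0.15)
    w <- stats::rlnorm(length(ids), 0, 1)
    blend_in(comp, stats::setNames(mass * w / sum(w), ids))
  }
  draw_depth <- function() {
    max(1, stats::rnbinom(1, size = config$read_depth_dispersion,
                          mu = config$read_depth_mean))
  }
  add_contamination <- function(comp) {
    if (!config$contamination) return(comp)
    hit <- stats::runif(length(contam_ids)) < config$contaminant_specimen_prob
    if (!any(hit)) return(comp)
    extra <- stats::setNames(rep(config$contaminant_relabund, sum(hit)),
                             contam_ids[hit])
    blend_in(comp, extra)
  }
  sample_specimen <- function(comp, depth) {
    as.integer(stats::rmultinom(1, depth, comp))
  }

  for (cc in couple_configs) {
    cid <- cc$couple_id
    f_id <- paste0(cid, "F"); m_id <- paste0(cid, "M")
    female_by_couple[cid] <- f_id; male_by_couple[cid] <- m_id
    cst_by_female[cid] <- cc$cst
    eff_fm <- cc$transfer_fm * if (cc$condom) cc$condom_factor_fm else 1
    eff_mf <- cc$transfer_mf * if (cc$condom) cc$condom_factor_mf else 1

    f_before <- if (cc$cst == "IV") {
      draw_community(pool, c("vaginal", "shared"), c(8, 12),
                     exclude_species = unname(cst_species))
    } else {
      draw_community(pool, c("vaginal", "shared"), c(5, 9),
                     dominant_species = cst_species[[cc$cst]])
    }
    f_before <- add_personal(expand_comp(f_before), f_id)
    m_before <- add_personal(
      expand_comp(draw_community(pool, c("penile_skin", "shared"),
                                 c(15, 22))), m_id)

    m_after <- (1 - eff_fm) * m_before + eff_fm * f_before
    f_after <- (1 - eff_mf) * f_before + eff_mf * m_before
    if (cc$n_introduced > 0) {
      intro <- env_pool[sample(nrow(env_pool), min(cc$n_introduced,
                                                   nrow(env_pool))), ]
      eps <- stats::setNames(
        stats::runif(nrow(intro), 0.002, 0.008), intro$asv_id)
      m_after <- blend_in(m_after, eps)
      f_after <- blend_in(f_after, eps)
    }

    # contaminated versions are what actually gets sequenced
    cf_before <- add_contamination(f_before)
    cf_after <- add_contamination(f_after)
    cm_before <- add_contamination(m_before)
    cm_after <- add_contamination(m_after)
    comps <- list(
      list(id = paste0(cid, "_F_before"), part = f_id, sex = "female",
           tp = "before", comp = cf_before),
      list(id = paste0(cid, "_F_after"), part = f_id, sex = "female",
           tp = "after", comp = cf_after),
      list(id = paste0(cid, "_M_before"), part = m_id, sex = "male",
           tp = "before", comp = cm_before),
      list(id = paste0(cid, "_M_after"), part = m_id, sex = "male",
           tp = "after", comp = cm_after))
    depths <- stats::setNames(
      vapply(comps, function(s) draw_depth(), numeric(1)),
      vapply(comps, `[[`, character(1), "id"))
    for (s in comps) {
      col <- sample_specimen(s$comp, depths[s$id])
      counts <- cbind(counts, col)
      colnames(counts)[ncol(counts)] <- s$id
      metadata[[s$id]] <- data.frame(
        sample_id = s$id, participant_id = s$part, couple_id = cid,
        sex = s$sex, timepoint = s$tp, sample_class = "specimen")
    }
    supports[[f_id]] <- data.frame(participant_id = f_id,
                                   asv_id = names(f_before)[f_before > 0])
    supports[[m_id]] <- data.frame(participant_id = m_id,
                                   asv_id = names(m_before)[m_before > 0])

    # planted transfers: candidates from the true (uncontaminated)
    # communities; detection probabilities from the sequenced compositions
    plant_direction <- function(true_donor, true_recip, seq_donor,
                                seq_after, direction, donor_before_id,
                                after_id, m) {
      if (m <= 0) return(NULL)
      cand <- names(true_donor)[true_donor > 0 & true_recip == 0]
      if (length(cand) == 0) return(NULL)
      p_donor_seen <- 1 - (1 - seq_donor[cand])^depths[donor_before_id]
      p_after_seen <- 1 - (1 - seq_after[cand])^depths[after_id]
      data.frame(couple_id = cid, direction = direction, asv_id = cand,
                 mixing_proportion = m,
                 detection_probability = unname(p_donor_seen * p_after_seen))
    }
    planted[[paste0(cid, "_fm")]] <- plant_direction(
      f_before, m_before, cf_before, cm_after, "female_to_male",
      paste0(cid, "_F_before"), paste0(cid, "_M_after"), eff_fm)
    planted[[paste0(cid, "_mf")]] <- plant_direction(
      m_before, f_before, cm_before, cf_after, "male_to_female",
      paste0(cid, "_M_before"), paste0(cid, "_F_after"), eff_mf)
    mixing[[cid]] <- data.frame(
      couple_id = cid, cst = cc$cst, transfer_fm = eff_fm,
      transfer_mf = eff_mf, n_introduced = cc$n_introduced,
      condom = cc$condom)
  }

  # controls: extraction blanks carry the kitome, NTCs are near-empty
  for (b in seq_len(config$n_extraction_blanks)) {
    id <- sprintf("BLANK%d", b)
    present <- stats::runif(length(contam_ids)) <
      config$contaminant_control_prob
    col <- rep(0L, n_taxa)
    if (any(present)) {
      w <- stats::rlnorm(sum(present), 0, 1)
      depth <- max(1, stats::rnbinom(1, size = 5, mu = 400))
      comp <- stats::setNames(numeric(n_taxa), taxa$asv_id)
      comp[contam_ids[present]] <- w / sum(w)
      col <- as.integer(stats::rmultinom(1, depth, comp))
    }
    counts <- cbind(counts, col)
    colnames(counts)[ncol(counts)] <- id
    metadata[[id]] <- data.frame(
      sample_id = id, participant_id = NA, couple_id = NA, sex = NA,
      timepoint = NA, sample_class = "extraction_blank")
  }
  for (b in seq_len(config$n_ntc)) {
    id <- sprintf("NTC%d", b)
    depth <- stats::rpois(1, 2)
    col <- rep(0L, n_taxa)
    if (depth > 0) {
      comp <- stats::setNames(numeric(n_taxa), taxa$asv_id)
      comp[contam_ids] <- 1 / length(contam_ids)
      col <- as.integer(stats::rmultinom(1, depth, comp))
    }
    counts <- cbind(counts, col)
    colnames(counts)[ncol(counts)] <- id
    metadata[[id]] <- data.frame(
      sample_id = id, participant_id = NA, couple_id = NA, sex = NA,
      timepoint = NA, sample_class = "no_template_control")
  }
  if (config$include_mock) {
    id <- "MOCK1"
    prof <- mock_observed_profile()
    comp <- stats::setNames(numeric(n_taxa), taxa$asv_id)
    comp[taxa$asv_id[match(names(prof), taxa$species)]] <-
      prof / sum(prof)
    col <- as.integer(stats::rmultinom(1, config$mock_depth, comp))
    counts <- cbind(counts, col)
    colnames(counts)[ncol(counts)] <- id
    metadata[[id]] <- data.frame(
      sample_id = id, participant_id = NA, couple_id = NA, sex = NA,
      timepoint = NA, sample_class = "mock")
  }

  storage.mode(counts) <- "integer"
  metadata <- do.call(rbind, metadata)
  rownames(metadata) <- NULL
  taxonomy <- make_taxonomy(taxa$asv_id, taxa$species)
  sequences <- NULL
  if (config$generate_sequences) {
    sequences <- stats::setNames(
      vapply(seq_len(n_taxa), function(i) {
        paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
              collapse = "")
      }, character(1)),
      taxa$asv_id)
  }
  dataset <- cohort_dataset(counts, taxonomy, metadata, sequences)
  planted <- do.call(rbind, planted[!vapply(planted, is.null, logical(1))])
  if (is.null(planted)) {
    planted <- data.frame(couple_id = character(0), direction = character(0),
                          asv_id = character(0),
                          mixing_proportion = numeric(0),
                          detection_probability = numeric(0))
  }
  rownames(planted) <- NULL
  true_supports <- do.call(rbind, supports)
  rownames(true_supports) <- NULL
  ground_truth <- structure(
    list(planted_transfers = planted,
         contaminants = contam_ids,
         cst_by_female = cst_by_female,
         mixing = do.call(rbind, c(mixing, list(make.row.names = FALSE))),
         true_supports = true_supports,
         female_by_couple = female_by_couple,
         male_by_couple = male_by_couple,
         config = config),
    class = "ground_truth")
  list(dataset = dataset, ground_truth = ground_truth)
}

#' Write a simulated cohort and its ground truth to disk
#'
#' Emits the standard cohort TSV/FASTA files via [write_cohort()] plus
#' `ground_truth.tsv` (planted transfers) and `simulation_config.json`.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory.
#' @return invisibly, the vector of paths written.
#' @export
write_simulation <- function(sim, dir) {
  paths <- write_cohort(sim$dataset, dir)
  gt <- file.path(dir, "ground_truth.tsv")
  write_tsv(sim$ground_truth$planted_transfers, gt)
  cfg <- file.path(dir, "simulation_config.json")
  jsonlite::write_json(unclass(sim$ground_truth$config), cfg,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, ground_truth = gt, config = cfg))
}

#' Build a mock-community sample and its expectation table
#'
#' Draws a multinomial read sample of the 8-species mock community and
#' returns it with the matching expected profile, for exercising the
#' quality-control comparator.
#'
#' @param proportions named proportions over the eight mock taxa (default
#'   uniform, 12.5% each); renormalized to sum to 1.
#' @param depth total reads to draw (>= 1).
#' @return list with `column` (named integer read counts) and `expected`
#'   (data.frame `taxon`, `proportion`).
#' @export
make_mock_fixture <- function(proportions = NULL, depth = 27993) {
  if (is.null(proportions)) {
    proportions <- stats::setNames(rep(1 / 8, 8), mock_taxa)
  }
  if (depth < 1) sexome_stop("depth must be >= 1", "sexome_invalid_config")
  if (any(proportions < 0) || sum(proportions) <= 0) {
    sexome_stop("proportions must be non-negative with positive sum",
                "sexome_invalid_config")
  }
  p <- proportions / sum(proportions)
  column <- stats::setNames(
    as.integer(stats::rmultinom(1, depth, p)), names(p))
  list(column = column,
       expected = data.frame(taxon = names(p), proportion = unname(p)))
}

#' Compare an observed mock-community sample with its expectation
#'
#' @param observed named counts (or proportions) of the observed mock
#'   sample.
#' @param expected expectation: data.frame (`taxon`, `proportion`) or a
#'   named proportion vector.
#' @return list with `per_taxon` (data.frame: taxon, expected, observed,
#'   abs_deviation), `off_target` (total observed proportion of taxa not in
#'   the expectation) and `max_deviation`.
#' @export
evaluate_mock <- function(observed, expected) {
  if (is.data.frame(expected)) {
    expected <- stats::setNames(expected$proportion, expected$taxon)
  }
  expected <- expected / sum(expected)
  obs <- observed / sum(observed)
  on_target <- stats::setNames(
    ifelse(names(expected) %in% names(obs), obs[names(expected)], 0),
    names(expected))
  on_target[is.na(on_target)] <- 0
  per_taxon <- data.frame(
    taxon = names(expected),
    expected = unname(expected),
    observed = unname(on_target),
    abs_deviation = abs(unname(on_target - expected)))
  off_target <- sum(obs[!names(obs) %in% names(expected)])
  list(per_taxon = per_taxon, off_target = off_target,
       max_deviation = max(per_taxon$abs_deviation))
}
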