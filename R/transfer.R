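# Directional bacterial-transfer classification for couple-paired
# before/after samples. Presence means >= `min_reads` reads (default 1).

# Observed taxon support of one sample.
sample_support <- function(dataset, sample_id, min_reads = 1) {
  rownames(dataset$counts)[dataset$counts[, sample_id] >= min_reads]
}

#' Baseline community of every participant
#'
#' A participant's baseline community is the set of ASVs detected in both
#' of their samples — before and after intercourse. Taxa present at only
#' one timepoint (gained or lost across the encounter) are excluded by
#' construction.
#'
#' @param dataset a `cohort_dataset` in which every participant has exactly
#'   one before and one after specimen.
#' @param min_reads minimum reads for presence.
#' @return data.frame with columns `participant_id`, `couple_id`, `sex`,
#'   `asv_id`, one row per baseline member.
#' @export
baseline_communities <- function(dataset, min_reads = 1) {
  md <- dataset$metadata[dataset$metadata$sample_class == "specimen", ]
  out <- list()
  for (p in unique(md$participant_id)) {
    rows <- md[md$participant_id == p, ]
    before <- rows$sample_id[rows$timepoint == "before"]
    after <- rows$sample_id[rows$timepoint == "after"]
    if (length(before) != 1 || length(after) != 1) {
      sexome_stop(paste0("participant ", p,
                         " lacks a before/after pair of specimens"),
                  "sexome_missing_timepoint")
    }
    base <- intersect(sample_support(dataset, before, min_reads),
                      sample_support(dataset, after, min_reads))
    if (length(base) > 0) {
      out[[p]] <- data.frame(participant_id = p,
                             couple_id = rows$couple_id[1],
                             sex = rows$sex[1],
                             asv_id = base)
    }
  }
  res <- if (length(out) == 0) {
    data.frame(participant_id = character(0), couple_id = character(0),
               sex = character(0), asv_id = character(0))
  } else {
    do.call(rbind, out)
  }
  rownames(res) <- NULL
  attr(res, "participants") <- unique(md$participant_id)
  res
}

#' Cohort-uniqueness flags for baseline ASVs
#'
#' An ASV is unique to a participant when it occurs in that participant's
#' baseline community and in no other participant's baseline across the
#' cohort.
#'
#' @param baselines data.frame from [baseline_communities()] (>= 2
#'   participants).
#' @return the input with an added logical column `cohort_unique`.
#' @export
cohort_unique_flags <- function(baselines) {
  participants <- attr(baselines, "participants") %||%
    unique(baselines$participant_id)
  if (length(participants) < 2) {
    sexome_stop("uniqueness needs at least two participants",
                "sexome_invalid_metadata")
  }
  occ <- table(baselines$asv_id)
  baselines$cohort_unique <- occ[baselines$asv_id] == 1
  baselines$cohort_unique <- as.logical(baselines$cohort_unique)
  baselines
}

#' Classify the after-intercourse ASVs of one couple
#'
#' For each partner's after sample, every detected ASV is assigned exactly
#' one category relative to the two before samples:
#' * `retained` — present in the recipient's own before sample;
#' * `transferred` — absent from the recipient's before sample but present
#'   in the partner's before sample (the direct transfer signature);
#' * `introduced` — absent from both before samples (environmental or
#'   other-body-site origin).
#' ASVs present before but undetected after are reported as `lost`.
#'
#' @param dataset a `cohort_dataset`.
#' @param couple a couple identifier with all four specimens present.
#' @param min_reads minimum reads for presence.
#' @return data.frame with columns `couple_id`, `recipient_sex`,
#'   `direction`, `asv_id`, `category`, `donor_before_abundance`,
#'   `recipient_after_abundance` (relative proportions; NA where the sample
#'   lacks the ASV).
#' @export
classify_after_asvs <- function(dataset, couple, min_reads = 1) {
  ids <- c(fb = sample_for(dataset, couple, "female", "before"),
           fa = sample_for(dataset, couple, "female", "after"),
           mb = sample_for(dataset, couple, "male", "before"),
           ma = sample_for(dataset, couple, "male", "after"))
  if (anyNA(ids)) {
    sexome_stop(paste0("couple ", couple,
                       " lacks one of its four specimens"),
                "sexome_missing_timepoint")
  }
  sup <- lapply(ids, function(s) sample_support(dataset, s, min_reads))
  rel <- function(s) {
    col <- dataset$counts[, s]
    tot <- sum(col)
    if (tot == 0) col * 0 else col / tot
  }
  one_side <- function(own_before, own_after, partner_before,
                       recipient_sex, donor_before_id, after_id) {
    after <- sup[[own_after]]
    category <- ifelse(after %in% sup[[own_before]], "retained",
                       ifelse(after %in% sup[[partner_before]],
                              "transferred", "introduced"))
    lost <- setdiff(sup[[own_before]], after)
    donor_rel <- rel(ids[donor_before_id])
    after_rel <- rel(ids[after_id])
    rbind(
      data.frame(couple_id = couple, recipient_sex = recipient_sex,
                 direction = if (recipient_sex == "male")
                   "female_to_male" else "male_to_female",
                 asv_id = after, category = category,
                 donor_before_abundance = ifelse(
                   category == "transferred", donor_rel[after], NA_real_),
                 recipient_after_abundance = after_rel[after]),
      if (length(lost) > 0)
        data.frame(couple_id = couple, recipient_sex = recipient_sex,
                   direction = if (recipient_sex == "male")
                     "female_to_male" else "male_to_female",
                   asv_id = lost, category = "lost",
                   donor_before_abundance = NA_real_,
                   recipient_after_abundance = NA_real_))
  }
  res <- rbind(
    one_side("mb", "ma", "fb", "male", "fb", "ma"),
    one_side("fb", "fa", "mb", "female", "mb", "fa"))
  rownames(res) <- NULL
  res
}

# Before-intercourse support sets in the same layout as
# baseline_communities(), for the before-support uniqueness variant.
before_support_table <- function(dataset, min_reads = 1) {
  md <- dataset$metadata[dataset$metadata$sample_class == "specimen" &
                           dataset$metadata$timepoint == "before", ]
  out <- lapply(seq_len(nrow(md)), function(i) {
    sup <- sample_support(dataset, md$sample_id[i], min_reads)
    if (length(sup) == 0) return(NULL)
    data.frame(participant_id = md$participant_id[i],
               couple_id = md$couple_id[i], sex = md$sex[i], asv_id = sup)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Uniqueness of a transferred ASV with respect to its donor: the ASV sits
# in the donor's baseline (or before support, by option) and in no other
# participant's, the recipient excepted.
transfer_is_unique <- function(asv, donor, recipient, baselines) {
  members <- baselines$participant_id[baselines$asv_id == asv]
  donor %in% members && !any(!members %in% c(donor, recipient))
}

#' Summarize one couple's baseline and transfer counts
#'
#' Builds the per-couple row of the cohort transfer table: baseline totals
#' and cohort-unique counts for each partner, directional transfer totals
#' and unique-transfer counts, and the corresponding percentages
#' (100 x unique / total, rounded half away from zero to one decimal; `NA`
#' when the total is zero). Transfer uniqueness is assessed with respect to
#' the donor against every other participant's baseline, the recipient
#' excepted.
#'
#' @param couple couple identifier.
#' @param classification data.frame from [classify_after_asvs()] for this
#'   couple.
#' @param baselines data.frame from [cohort_unique_flags()] for the whole
#'   cohort.
#' @param transfer_reference membership table against which transfer
#'   uniqueness is assessed; defaults to `baselines`. Supplying the raw
#'   before-support table instead gives the before-support uniqueness
#'   variant for sensitivity analysis.
#' @return one-row data.frame with 13 columns: `couple_id`;
#'   `female_baseline_total/unique/pct`; `male_baseline_total/unique/pct`;
#'   `f2m_transfer_total/unique/pct`; `m2f_transfer_total/unique/pct`.
#' @export
summarize_couple <- function(couple, classification, baselines,
                             transfer_reference = NULL) {
  transfer_reference <- transfer_reference %||% baselines
  stopifnot("cohort_unique" %in% names(baselines))
  pct <- function(unique_n, total_n) {
    if (total_n == 0) NA_real_ else round_half_up(100 * unique_n / total_n, 1)
  }
  base_side <- function(sex) {
    b <- baselines[baselines$couple_id == couple & baselines$sex == sex, ]
    c(total = nrow(b), unique = sum(b$cohort_unique))
  }
  couple_parts <- baselines[baselines$couple_id == couple, ]
  participant_of <- function(sex) {
    p <- unique(couple_parts$participant_id[couple_parts$sex == sex])
    if (length(p) == 1) p else NA_character_
  }
  transfer_side <- function(direction) {
    donor_sex <- if (direction == "female_to_male") "female" else "male"
    recipient_sex <- if (direction == "female_to_male") "male" else "female"
    tr <- classification[classification$direction == direction &
                           classification$category == "transferred", ]
    donor <- participant_of(donor_sex)
    recipient <- participant_of(recipient_sex)
    uniq <- if (nrow(tr) == 0) 0L else
      sum(vapply(tr$asv_id, transfer_is_unique, logical(1),
                 donor = donor, recipient = recipient,
                 baselines = transfer_reference))
    c(total = nrow(tr), unique = uniq)
  }
  f <- base_side("female"); m <- base_side("male")
  fm <- transfer_side("female_to_male"); mf <- transfer_side("male_to_female")
  data.frame(
    couple_id = couple,
    female_baseline_total = f[["total"]],
    female_baseline_unique = f[["unique"]],
    female_baseline_pct = pct(f[["unique"]], f[["total"]]),
    male_baseline_total = m[["total"]],
    male_baseline_unique = m[["unique"]],
    male_baseline_pct = pct(m[["unique"]], m[["total"]]),
    f2m_transfer_total = fm[["total"]],
    f2m_transfer_unique = fm[["unique"]],
    f2m_transfer_pct = pct(fm[["unique"]], fm[["total"]]),
    m2f_transfer_total = mf[["total"]],
    m2f_transfer_unique = mf[["unique"]],
    m2f_transfer_pct = pct(mf[["unique"]], mf[["total"]]))
}

#' Cohort-wide transfer summary table
#'
#' Runs [baseline_communities()], [cohort_unique_flags()],
#' [classify_after_asvs()] and [summarize_couple()] over every couple and
#' returns the stacked per-couple summary plus the full classification.
#'
#' @param dataset a `cohort_dataset`.
#' @param min_reads minimum reads for presence.
#' @param unique_on evaluate transfer uniqueness against `"baseline"`
#'   communities (default) or raw `"before_support"` sets.
#' @return list with `summary` (one row per couple), `classification`
#'   (all per-ASV calls) and `baselines` (flagged baseline membership).
#' @export
transfer_summary <- function(dataset, min_reads = 1,
                             unique_on = c("baseline", "before_support")) {
  unique_on <- match.arg(unique_on)
  baselines <- cohort_unique_flags(baseline_communities(dataset, min_reads))
  transfer_reference <- if (unique_on == "baseline") baselines else
    before_support_table(dataset, min_reads)
  md <- dataset$metadata
  couples <- unique(stats::na.omit(md$couple_id[md$sample_class == "specimen"]))
  cls <- do.call(rbind, lapply(couples, classify_after_asvs,
                               dataset = dataset, min_reads = min_reads))
  summ <- do.call(rbind, lapply(couples, function(cp) {
    summarize_couple(cp, cls[cls$couple_id == cp, ], baselines,
                     transfer_reference = transfer_reference)
  }))
  rownames(summ) <- NULL
  list(summary = summ, classification = cls, baselines = baselines)
}

#' Contributor genera for one couple
#'
#' A genus is a *male contributor* when its relative abundance falls in the
#' male partner across intercourse and rises in the female partner (both
#' beyond a tolerance `delta`), indicating net movement male to female; a
#' *female contributor* is the mirror case.
#'
#' @param genus_rel matrix of genus-level relative abundances with the four
#'   couple samples as columns, named (or supplied in the order)
#'   `female_before`, `female_after`, `male_before`, `male_after`.
#' @param delta tolerance on the abundance change, in absolute proportion
#'   units (default 0.005 = 0.5 percentage points) to suppress
#'   counting noise; set 0 for pure strictness.
#' @return data.frame: `genus`, `direction`
#'   (`male_contributor`/`female_contributor`/`none`), `male_delta`,
#'   `female_delta` (after minus before).
#' @export
contributor_genera <- function(genus_rel, delta = 0.005) {
  need <- c("female_before", "female_after", "male_before", "male_after")
  if (is.null(colnames(genus_rel))) colnames(genus_rel) <- need
  if (!all(need %in% colnames(genus_rel))) {
    sexome_stop("genus_rel must have the four couple sample columns",
                "sexome_invalid_counts")
  }
  male_delta <- genus_rel[, "male_after"] - genus_rel[, "male_before"]
  female_delta <- genus_rel[, "female_after"] - genus_rel[, "female_before"]
  direction <- ifelse(male_delta < -delta & female_delta > delta,
                      "male_contributor",
                      ifelse(female_delta < -delta & male_delta > delta,
                             "female_contributor", "none"))
  data.frame(genus = rownames(genus_rel), direction = direction,
             male_delta = male_delta, female_delta = female_delta,
             row.names = NULL)
}

#' Cohort-level contributor genera from group means
#'
#' Applies the contributor rule to the mean relative abundance of each
#' genus in the four sex-by-timepoint groups, mirroring the grouped heatmap
#' view of the cohort.
#'
#' @param dataset a `cohort_dataset`.
#' @param delta tolerance as in [contributor_genera()].
#' @return data.frame as in [contributor_genera()].
#' @export
cohort_contributors <- function(dataset, delta = 0.005) {
  hm <- export_group_heatmap_data(dataset)
  m <- as.matrix(hm[, c("female_before", "female_after",
                        "male_before", "male_after")])
  rownames(m) <- hm$taxon
  contributor_genera(m, delta)
}

#' Compare transfer calls against simulation ground truth
#'
#' Sensitivity is the fraction of confidently detectable planted transfers
#' (closed-form detection probability at the drawn read depth at least
#' `detection_threshold`) recovered by the transfer engine. Calls that were
#' not planted are split into *explainable* ones — the taxon truly lived in
#' the recipient's before community but dropped out of that sample at
#' finite depth (a shared-niche artifact), or is a planted reagent
#' contaminant — and unexplainable false positives.
#'
#' @param calls classification data.frame from [classify_after_asvs()] /
#'   [transfer_summary()].
#' @param truth `ground_truth` from [simulate_cohort()].
#' @param detection_threshold minimum closed-form detection probability for
#'   a planted transfer to count as detectable (default 0.99).
#' @return list: `sensitivity`, `n_detectable`, `n_recovered`,
#'   `false_positives` (unexplainable calls), `explainable` (dropout or
#'   sub-threshold calls).
#' @export
transfer_recovery_report <- function(calls, truth,
                                     detection_threshold = 0.99) {
  planted <- truth$planted_transfers
  tr <- calls[calls$category == "transferred", , drop = FALSE]
  bad_couples <- setdiff(tr$couple_id, planted$couple_id)
  if (nrow(planted) > 0 && length(bad_couples) > 0) {
    sexome_stop(paste0("calls reference couples absent from ground truth: ",
                       paste(bad_couples, collapse = ", ")),
                "sexome_crossref_mismatch")
  }
  key <- function(df) paste(df$couple_id, df$direction, df$asv_id)
  detectable <- planted[planted$detection_probability >=
                          detection_threshold, , drop = FALSE]
  recovered <- key(detectable) %in% key(tr)
  extra <- tr[!key(tr) %in% key(planted), , drop = FALSE]
  true_before <- truth$true_supports
  explainable <- logical(nrow(extra))
  if (nrow(extra) > 0 && !is.null(true_before)) {
    tkey <- paste(true_before$participant_id, true_before$asv_id)
    recipient <- ifelse(extra$direction == "female_to_male",
                        truth$male_by_couple[extra$couple_id],
                        truth$female_by_couple[extra$couple_id])
    explainable <- paste(recipient, extra$asv_id) %in% tkey |
      extra$asv_id %in% truth$contaminants
  }
  list(
    sensitivity = if (nrow(detectable) == 0) NA_real_ else mean(recovered),
    n_detectable = nrow(detectable),
    n_recovered = sum(recovered),
    false_positives = extra[!explainable, , drop = FALSE],
    explainable = extra[explainable, , drop = FALSE])
}
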