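#' Mean relative abundance by taxon and sex-by-timepoint group
#'
#' Aggregates specimen counts at a taxonomic rank, converts each specimen
#' to relative abundances, and averages within the four groups (female/male
#' x before/after) — the data behind the grouped composition heatmap used
#' to identify the genera driving the diversity disruption.
#'
#' @param dataset a `cohort_dataset`.
#' @param rank taxonomic rank to aggregate at (default `"genus"`).
#' @return data.frame: `taxon`, `female_before`, `female_after`,
#'   `male_before`, `male_after`, sorted by overall mean abundance.
#' @export
export_group_heatmap_data <- function(dataset, rank = "genus") {
  agg <- aggregate_by_rank(dataset, rank)
  spec <- specimen_ids(dataset)
  rel <- to_relative_abundance(agg[, spec, drop = FALSE])
  md <- dataset$metadata
  group_of <- paste(md$sex[match(spec, md$sample_id)],
                    md$timepoint[match(spec, md$sample_id)], sep = "_")
  groups <- c("female_before", "female_after", "male_before", "male_after")
  means <- vapply(groups, function(g) {
    cols <- which(group_of == g)
    if (length(cols) == 0) rep(NA_real_, nrow(rel)) else
      rowMeans(rel[, cols, drop = FALSE])
  }, numeric(nrow(rel)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(rel), groups))
  }
  out <- data.frame(taxon = rownames(rel), means, row.names = NULL)
  out[order(-rowMeans(means, na.rm = TRUE)), , drop = FALSE]
}

#' Per-sample composition tables for one couple
#'
#' Emits, for each of the couple's four samples, the table of detected
#' ASVs with genus assignment and within-sample relative abundance — the
#' data rendered by circle-packing composition figures.
#'
#' @param dataset a `cohort_dataset`.
#' @param couple couple identifier.
#' @param dir optional directory; when given, one TSV per sample is
#'   written.
#' @return named list of four data.frames (`female_before`,
#'   `female_after`, `male_before`, `male_after`) with columns `asv_id`,
#'   `genus`, `relative_abundance`.
#' @export
export_couple_composition <- function(dataset, couple, dir = NULL) {
  md <- dataset$metadata
  if (!couple %in% md$couple_id[md$sample_class == "specimen"]) {
    sexome_stop(paste0("unknown couple: ", couple), "sexome_unknown_couple")
  }
  cells <- expand.grid(sex = c("female", "male"),
                       timepoint = c("before", "after"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    nm <- paste(cells$sex[i], cells$timepoint[i], sep = "_")
    sid <- sample_for(dataset, couple, cells$sex[i], cells$timepoint[i])
    col <- dataset$counts[, sid]
    keep <- col > 0
    if (!any(keep)) {
      warning("sample ", sid, " has no detected ASVs")
      out[[nm]] <- data.frame(asv_id = character(0), genus = character(0),
                              relative_abundance = numeric(0))
      next
    }
    genus <- dataset$taxonomy$genus[match(names(col)[keep],
                                          dataset$taxonomy$asv_id)]
    out[[nm]] <- data.frame(asv_id = names(col)[keep], genus = genus,
                            relative_abundance = col[keep] / sum(col),
                            row.names = NULL)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write_tsv(out[[nm]],
                file.path(dir, sprintf("composition_%s_%s.tsv", couple, nm)))
    }
  }
  out
}

#' Default pipeline configuration
#'
#' @param ... overrides of the default keys: input paths (`counts`,
#'   `taxonomy`, `metadata`, `sequences`) or `simulate = TRUE` with
#'   `n_couples`/`read_depth_mean`/`contamination`; thresholds
#'   (`decontam_threshold`, `relabund_threshold`, `cst_threshold`,
#'   `min_reads_presence`, `contributor_delta`); `permutations`; `seed`;
#'   `alpha_filtered` (apply the relative-abundance filter before alpha
#'   diversity too; off by default, the filter is scoped to ordination).
#' @return named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    counts = NULL, taxonomy = NULL, metadata = NULL, sequences = NULL,
    simulate = FALSE, n_couples = 12, read_depth_mean = 8292,
    contamination = TRUE,
    decontam_threshold = 0.05, relabund_threshold = 0.001,
    cst_threshold = 0.30, min_reads_presence = 1,
    contributor_delta = 0.005, permutations = 999,
    alpha_filtered = FALSE, seed = 1)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    sexome_stop(paste0("unknown config key(s): ",
                       paste(unknown, collapse = ", ")),
                "sexome_invalid_config")
  }
  utils::modifyList(cfg, over)
}

#' Read a pipeline configuration from a flat YAML file
#'
#' @param path YAML file of `key: value` pairs (keys as in
#'   [pipeline_config()]).
#' @return configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    sexome_stop(paste0("file not found: ", path), "sexome_missing_file")
  }
  do.call(pipeline_config, yaml::read_yaml(path))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    sexome_stop(sprintf("stage '%s' failed: %s", stage,
                        conditionMessage(e)),
                "sexome_stage_error")
  })
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order — contaminant identification and removal,
#' alpha diversity, low-abundance filtering scoped to ordination,
#' Bray-Curtis / PCoA / PERMANOVA (sex and couple, 999 permutations by
#' default), community state typing of female before samples, and the
#' directional transfer analysis — writing every tabular output plus a
#' machine-readable run manifest to `outdir`. Reruns with the same
#' configuration reproduce byte-identical numeric outputs.
#'
#' @param config list from [pipeline_config()] /
#'   [read_pipeline_config()], or a path to a YAML config file.
#' @param outdir output directory.
#' @return invisibly, a list with the in-memory stage results
#'   (`dataset`, `contaminants`, `alpha`, `ordination`, `permanova`,
#'   `cst`, `transfer`, `contributors`, `files`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    write_tsv(df, path)
    files[[name]] <<- path
  }

  dataset <- run_stage("input", {
    if (isTRUE(config$simulate)) {
      simulate_cohort(simulation_config(
        n_couples = config$n_couples,
        read_depth_mean = config$read_depth_mean,
        contamination = config$contamination,
        seed = config$seed))$dataset
    } else {
      read_cohort(config$counts, config$taxonomy, config$metadata,
                  config$sequences)
    }
  })

  contaminants <- run_stage("contam_filter", {
    identify_contaminants(dataset, config$decontam_threshold,
                          min_reads = config$min_reads_presence)
  })
  emit(contaminants, "contaminants.tsv")
  clean <- run_stage("contam_filter", remove_contaminants(dataset,
                                                          contaminants))

  alpha <- run_stage("alpha_diversity", {
    ds <- if (isTRUE(config$alpha_filtered)) {
      filter_low_abundance(clean, config$relabund_threshold)
    } else clean
    alpha_table(ds, "sex")
  })
  emit(alpha$samples, "alpha_diversity.tsv")
  emit(alpha$comparisons, "alpha_comparisons.tsv")

  ordination <- run_stage("beta_diversity", {
    filtered <- filter_low_abundance(clean, config$relabund_threshold)
    spec <- specimen_ids(filtered)
    d <- bray_curtis_matrix(filtered$counts[, spec, drop = FALSE])
    list(distance = d, pcoa = pcoa(d), sample_ids = spec,
         metadata = filtered$metadata)
  })
  emit(data.frame(sample_id = rownames(ordination$distance),
                  ordination$distance, check.names = FALSE),
       "distance_matrix.tsv")
  emit(data.frame(sample_id = rownames(ordination$pcoa$coordinates),
                  ordination$pcoa$coordinates, check.names = FALSE),
       "pcoa_coordinates.tsv")
  emit(data.frame(axis = seq_along(ordination$pcoa$proportion_explained),
                  eigenvalue = ordination$pcoa$eigenvalues[
                    seq_along(ordination$pcoa$proportion_explained)],
                  proportion_explained =
                    ordination$pcoa$proportion_explained),
       "pcoa_eigen.tsv")

  perm <- run_stage("permanova", {
    md <- ordination$metadata
    labels_for <- function(field) {
      md[[field]][match(ordination$sample_ids, md$sample_id)]
    }
    lapply(c(sex = "sex", couple = "couple_id"), function(field) {
      permanova(ordination$distance, labels_for(field),
                n_permutations = config$permutations, seed = config$seed)
    })
  })
  emit(do.call(rbind, lapply(names(perm), function(f) {
    data.frame(factor = f, pseudo_F = perm[[f]]$pseudo_F,
               r_squared = perm[[f]]$r_squared,
               p_value = perm[[f]]$p_value,
               n_permutations = perm[[f]]$n_permutations)
  })), "permanova.tsv")

  cst <- run_stage("community_typing",
                   assign_cst_cohort(clean, config$cst_threshold))
  emit(cst, "cst.tsv")

  transfer <- run_stage("transfer_analysis",
                        transfer_summary(clean,
                                         config$min_reads_presence))
  calls <- transfer$classification
  calls <- calls[calls$category == "transferred", , drop = FALSE]
  if (nrow(calls) > 0) {
    md <- clean$metadata
    donor_sex <- ifelse(calls$direction == "female_to_male", "female",
                        "male")
    part_of <- function(couple, sex) {
      unique(md$participant_id[md$sample_class == "specimen" &
                                 md$couple_id == couple & md$sex == sex])
    }
    calls$cohort_unique <- vapply(seq_len(nrow(calls)), function(i) {
      transfer_is_unique(calls$asv_id[i],
                         part_of(calls$couple_id[i], donor_sex[i]),
                         part_of(calls$couple_id[i],
                                 calls$recipient_sex[i]),
                         transfer$baselines)
    }, logical(1))
  } else {
    calls$cohort_unique <- logical(0)
  }
  emit(calls[, c("couple_id", "direction", "asv_id", "cohort_unique",
                 "donor_before_abundance", "recipient_after_abundance")],
       "transfer_calls.tsv")
  emit(transfer$summary, "couple_summary.tsv")

  contributors <- run_stage("contributors",
                            cohort_contributors(clean,
                                                config$contributor_delta))
  emit(contributors, "contributors.tsv")
  emit(export_group_heatmap_data(clean), "heatmap_genus_groups.tsv")

  manifest <- list(
    package = "sexome",
    version = as.character(utils::packageVersion("sexome")),
    config = config,
    seed = config$seed,
    stages = list(
      input = list(n_asvs = nrow(dataset$counts),
                   n_samples = ncol(dataset$counts)),
      contam_filter = list(n_asvs = nrow(contaminants),
                           n_flagged = sum(contaminants$flagged)),
      alpha_diversity = list(n_rows = nrow(alpha$samples)),
      beta_diversity = list(n_samples = nrow(ordination$distance)),
      community_typing = list(n_rows = nrow(cst)),
      transfer_analysis = list(n_couples = nrow(transfer$summary))))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  files[["manifest.json"]] <- manifest_path

  invisible(list(dataset = dataset, contaminants = contaminants,
                 alpha = alpha, ordination = ordination, permanova = perm,
                 cst = cst, transfer = transfer,
                 contributors = contributors, files = files))
}
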