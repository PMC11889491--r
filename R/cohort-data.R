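#' Assemble and validate a cohort dataset
#'
#' Bundles the three core tables of a couple-paired before/after amplicon
#' study — the ASV count matrix, the taxonomy table and the sample metadata —
#' into a single validated object, optionally together with the ASV
#' sequences. All downstream stages (contaminant filtering, diversity,
#' community state typing, transfer analysis) operate on this object.
#'
#' @param counts integer matrix of read counts, ASVs as rows (rownames = ASV
#'   identifiers), samples as columns (colnames = sample identifiers).
#' @param taxonomy data.frame with columns `asv_id`, `kingdom`, `phylum`,
#'   `class`, `order`, `family`, `genus`, `species`; unassigned ranks carry
#'   the sentinel `"unclassified"`.
#' @param metadata data.frame with columns `sample_id`, `participant_id`,
#'   `couple_id`, `sex` (`male`/`female`), `timepoint` (`before`/`after`) and
#'   `sample_class` (`specimen`, `extraction_blank`, `no_template_control`,
#'   `mock`). Control records must have missing couple/sex/timepoint.
#' @param sequences optional named character vector of nucleotide sequences,
#'   one per ASV.
#' @return an object of class `cohort_dataset`: a list with elements
#'   `counts`, `taxonomy`, `metadata`, `sequences`.
#' @seealso [read_cohort()], [write_cohort()], [simulate_cohort()]
#' @export
cohort_dataset <- function(counts, taxonomy, metadata, sequences = NULL) {
  counts <- as.matrix(counts)
  validate_counts(counts)
  taxonomy <- validate_taxonomy(taxonomy, rownames(counts))
  metadata <- validate_metadata(metadata, colnames(counts))
  if (!is.null(sequences)) {
    seq_names <- names(sequences)
    sequences <- as.character(sequences)   # drops names; restore them
    names(sequences) <- seq_names
    missing_seq <- setdiff(rownames(counts), names(sequences))
    if (length(missing_seq) > 0) {
      sexome_stop(
        paste0("sequences missing for ASV(s): ",
               paste(utils::head(missing_seq, 5), collapse = ", ")),
        "sexome_crossref_mismatch")
    }
  }
  structure(
    list(counts = counts, taxonomy = taxonomy, metadata = metadata,
         sequences = sequences),
    class = "cohort_dataset")
}

validate_counts <- function(counts) {
  # R stores zero-length dimnames as NULL, so only non-degenerate extents
  # can demand names
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    sexome_stop("counts matrix must have ASV rownames and sample colnames",
                "sexome_invalid_counts")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    sexome_stop("duplicate ASV or sample identifiers in counts",
                "sexome_duplicate_ids")
  }
  if (anyNA(counts) || !is.numeric(counts)) {
    sexome_stop("counts must be numeric with no missing values",
                "sexome_invalid_counts")
  }
  bad <- which(counts < 0 | counts != round(counts), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    sexome_stop(
      sprintf("counts must be non-negative integers; first offender (%s, %s) = %s",
              rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
              format(counts[bad[1, 1], bad[1, 2]])),
      "sexome_invalid_counts")
  }
  invisible(counts)
}

tax_ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
               "species")

validate_taxonomy <- function(taxonomy, asv_ids) {
  need <- c("asv_id", tax_ranks)
  miss <- setdiff(need, names(taxonomy))
  if (length(miss) > 0) {
    sexome_stop(paste0("taxonomy is missing column(s): ",
                       paste(miss, collapse = ", ")),
                "sexome_invalid_taxonomy")
  }
  if (anyDuplicated(taxonomy$asv_id)) {
    sexome_stop("duplicate asv_id in taxonomy", "sexome_duplicate_ids")
  }
  uncovered <- setdiff(asv_ids, taxonomy$asv_id)
  if (length(uncovered) > 0) {
    sexome_stop(
      paste0("taxonomy has no entry for ASV(s): ",
             paste(utils::head(uncovered, 5), collapse = ", ")),
      "sexome_crossref_mismatch")
  }
  # normalise blank/NA ranks to the single sentinel
  for (r in tax_ranks) {
    v <- trimws(as.character(taxonomy[[r]]))
    v[is.na(v) | v == ""] <- "unclassified"
    taxonomy[[r]] <- v
  }
  taxonomy[match(asv_ids, taxonomy$asv_id), , drop = FALSE]
}

sample_classes <- c("specimen", "extraction_blank", "no_template_control",
                    "mock")

validate_metadata <- function(metadata, sample_ids) {
  need <- c("sample_id", "participant_id", "couple_id", "sex", "timepoint",
            "sample_class")
  miss <- setdiff(need, names(metadata))
  if (length(miss) > 0) {
    sexome_stop(paste0("metadata is missing column(s): ",
                       paste(miss, collapse = ", ")),
                "sexome_invalid_metadata")
  }
  if (anyDuplicated(metadata$sample_id)) {
    sexome_stop("duplicate sample_id in metadata", "sexome_duplicate_ids")
  }
  for (col in c("participant_id", "couple_id", "sex", "timepoint")) {
    v <- as.character(metadata[[col]])
    v[!is.na(v) & trimws(v) == ""] <- NA
    metadata[[col]] <- v
  }
  only_meta <- setdiff(metadata$sample_id, sample_ids)
  only_counts <- setdiff(sample_ids, metadata$sample_id)
  if (length(only_meta) + length(only_counts) > 0) {
    sexome_stop(
      paste0("metadata/counts sample mismatch; only in metadata: {",
             paste(only_meta, collapse = ", "), "}; only in counts: {",
             paste(only_counts, collapse = ", "), "}"),
      "sexome_crossref_mismatch")
  }
  if (!all(metadata$sample_class %in% sample_classes)) {
    sexome_stop(
      paste0("sample_class must be one of: ",
             paste(sample_classes, collapse = ", ")),
      "sexome_invalid_metadata")
  }
  spec <- metadata[metadata$sample_class == "specimen", , drop = FALSE]
  if (nrow(spec) > 0) {
    req <- c("participant_id", "couple_id", "sex", "timepoint")
    if (anyNA(spec[, req])) {
      sexome_stop("specimen records require participant, couple, sex and timepoint",
                  "sexome_invalid_metadata")
    }
    if (!all(spec$sex %in% c("male", "female")) ||
        !all(spec$timepoint %in% c("before", "after"))) {
      sexome_stop("sex must be male/female and timepoint before/after",
                  "sexome_invalid_metadata")
    }
    key <- paste(spec$couple_id, spec$sex, spec$timepoint)
    if (anyDuplicated(key)) {
      sexome_stop(
        paste0("more than one specimen for (couple, sex, timepoint): ",
               key[duplicated(key)][1]),
        "sexome_duplicate_specimen")
    }
  }
  ctrl <- metadata[metadata$sample_class != "specimen", , drop = FALSE]
  if (nrow(ctrl) > 0 &&
      !all(is.na(ctrl$couple_id) & is.na(ctrl$sex) & is.na(ctrl$timepoint))) {
    sexome_stop("control records must have missing couple, sex and timepoint",
                "sexome_invalid_metadata")
  }
  metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
}

#' Read a cohort dataset from disk
#'
#' Reads the three tab-separated tables (counts with first column `asv_id`
#' and one column per sample; taxonomy; metadata) and, optionally, ASV
#' sequences in FASTA, cross-validates them and returns a
#' [cohort_dataset()].
#'
#' @param counts_path,taxonomy_path,metadata_path paths to TSV files.
#' @param sequences_path optional path to a FASTA file keyed by ASV id
#'   (requires the Biostrings package).
#' @return a validated `cohort_dataset`.
#' @export
read_cohort <- function(counts_path, taxonomy_path, metadata_path,
                        sequences_path = NULL) {
  for (p in c(counts_path, taxonomy_path, metadata_path, sequences_path)) {
    if (!file.exists(p)) {
      sexome_stop(paste0("file not found: ", p), "sexome_missing_file")
    }
  }
  counts_df <- read_tsv(counts_path, colClasses = NA)
  if (names(counts_df)[1] != "asv_id") {
    sexome_stop("counts table must have 'asv_id' as its first column",
                "sexome_invalid_counts")
  }
  counts <- as.matrix(counts_df[, -1, drop = FALSE])
  if (!is.numeric(counts)) {
    sexome_stop("counts table contains non-numeric cells",
                "sexome_invalid_counts")
  }
  rownames(counts) <- as.character(counts_df$asv_id)
  taxonomy <- read_tsv(taxonomy_path)
  metadata <- read_tsv(metadata_path, na.strings = c("NA", ""))
  sequences <- NULL
  if (!is.null(sequences_path)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      sexome_stop("Biostrings is required to read FASTA sequences",
                  "sexome_missing_dependency")
    }
    ss <- Biostrings::readDNAStringSet(sequences_path)
    sequences <- as.character(ss)
    names(sequences) <- sub("\\s.*$", "", names(ss))
  }
  cohort_dataset(counts, taxonomy, metadata, sequences)
}

#' Write a cohort dataset to disk
#'
#' Emits `counts.tsv`, `taxonomy.tsv`, `metadata.tsv` and, when sequences
#' are present, `sequences.fasta`, in the same dialects [read_cohort()]
#' accepts, so that a write/read round trip reproduces the dataset
#' cell-for-cell.
#'
#' @param dataset a `cohort_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cohort_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(counts = file.path(dir, "counts.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             metadata = file.path(dir, "metadata.tsv"))
  counts_df <- data.frame(asv_id = rownames(dataset$counts),
                          dataset$counts, check.names = FALSE)
  write_tsv(counts_df, paths["counts"])
  write_tsv(dataset$taxonomy, paths["taxonomy"])
  write_tsv(dataset$metadata, paths["metadata"])
  if (!is.null(dataset$sequences)) {
    if (!requireNamespace("Biostrings", quietly = TRUE)) {
      sexome_stop("Biostrings is required to write FASTA sequences",
                  "sexome_missing_dependency")
    }
    paths <- c(paths, sequences = file.path(dir, "sequences.fasta"))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(dataset$sequences), paths["sequences"])
  }
  invisible(paths)
}

#' @export
print.cohort_dataset <- function(x, ...) {
  md <- x$metadata
  cat("cohort_dataset:", nrow(x$counts), "ASVs x", ncol(x$counts),
      "samples\n")
  cat("  specimens:", sum(md$sample_class == "specimen"),
      " controls:", sum(md$sample_class %in%
                          c("extraction_blank", "no_template_control")),
      " mock:", sum(md$sample_class == "mock"), "\n")
  if (any(md$sample_class == "specimen")) {
    cat("  couples:", length(unique(stats::na.omit(md$couple_id))), "\n")
  }
  cat("  total reads:", sum(x$counts),
      sprintf(" (mean/sample: %.0f)\n", mean(colSums(x$counts))))
  invisible(x)
}

# Convenience accessors used throughout the package -------------------------

specimen_ids <- function(dataset) {
  md <- dataset$metadata
  md$sample_id[md$sample_class == "specimen"]
}

control_ids <- function(dataset,
                        classes = c("extraction_blank",
                                    "no_template_control")) {
  md <- dataset$metadata
  md$sample_id[md$sample_class %in% classes]
}

# The single specimen for a (couple, sex, timepoint) cell; NA when absent.
sample_for <- function(dataset, couple, sex, timepoint) {
  md <- dataset$metadata
  id <- md$sample_id[md$sample_class == "specimen" &
                       md$couple_id == couple & md$sex == sex &
                       md$timepoint == timepoint]
  if (length(id) == 0) NA_character_ else id
}

# Subset a dataset to selected ASVs and/or samples (keeps validity).
# Degenerate subsets can drop matrix dimnames wholesale; restore them.
subset_cohort <- function(dataset, asvs = NULL, samples = NULL) {
  counts <- dataset$counts
  if (!is.null(asvs)) {
    cn <- colnames(counts)
    counts <- counts[asvs, , drop = FALSE]
    dimnames(counts) <- list(asvs, cn)
  }
  if (!is.null(samples)) {
    rn <- rownames(counts)
    counts <- counts[, samples, drop = FALSE]
    dimnames(counts) <- list(rn, samples)
  }
  taxonomy <- dataset$taxonomy[dataset$taxonomy$asv_id %in% rownames(counts), ,
                               drop = FALSE]
  metadata <- dataset$metadata[dataset$metadata$sample_id %in%
                                 colnames(counts), , drop = FALSE]
  sequences <- dataset$sequences
  if (!is.null(sequences)) sequences <- sequences[rownames(counts)]
  cohort_dataset(counts, taxonomy, metadata, sequences)
}
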