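# Text formats of the pipeline: a tab-delimited expression matrix (first
# column probe IDs, header row sample IDs) and a comma-delimited per-sample
# metadata table. Readers validate identifiers, types and vocabularies and
# report coordinates on failure.

.sampleTableRequired <- c("sample_id", "inflammation_grade", "fibrosis_stage",
                          "age_days", "sex", "clinical_type", "cholangitis",
                          "ascites", "followup_months", "event")

#' Read an expression matrix from tab-delimited text
#'
#' Expects a header row of sample IDs and a first column of probe IDs;
#' decimal points, no thousands separators. Duplicate identifiers and
#' non-numeric cells are rejected with coordinates.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix, probes x samples, with dimnames.
#' @export
readExpressionTSV <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- read.delim(path, check.names = FALSE, colClasses = "character",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a probe column and at least one sample: ", path)
  probes <- df[[1L]]
  samples <- colnames(df)[-1L]
  if (anyDuplicated(samples)) {
    stop("duplicated sample ID(s) in ", path, ": ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  if (anyDuplicated(probes)) {
    stop("duplicated probe ID(s) in ", path, ": ",
         paste(unique(probes[duplicated(probes)]), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA")), arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric expression value '%s' at probe '%s', sample '%s' in %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], probes[bad[1L, 1L]],
                 samples[bad[1L, 2L]], path))
  }
  if (anyNA(num)) stop("missing expression values are not supported: ", path)
  dimnames(num) <- list(probes, samples)
  num
}

#' Read a per-sample metadata table from comma-delimited text
#'
#' Requires columns `sample_id`, `inflammation_grade`, `fibrosis_stage`,
#' `age_days`, `sex`, `clinical_type`, `cholangitis`, `ascites`,
#' `followup_months`, `event`; extra columns (e.g. simulator truth) are kept.
#' Histology scores must lie in 0..3, flags in \{0, 1\}, `sex` in
#' \{female, male\}, `clinical_type` in \{perinatal, BASM\}. Missing values
#' are explicit empty cells and are never imputed.
#'
#' @param path path to the CSV file.
#' @return Typed `data.frame`, one row per sample.
#' @export
readSampleTable <- function(path) {
  if (!file.exists(path)) stop("sample table not found: ", path)
  df <- read.csv(path, check.names = FALSE, colClasses = "character",
                 stringsAsFactors = FALSE)
  missing <- setdiff(.sampleTableRequired, colnames(df))
  if (length(missing)) {
    stop("sample table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) < 1L) stop("sample table is empty: ", path)
  if (anyDuplicated(df$sample_id)) {
    stop("duplicated sample ID(s) in ", path, ": ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  }
  num <- function(col, integer = FALSE) {
    raw <- df[[col]]
    out <- suppressWarnings(as.numeric(raw))
    bad <- is.na(out) & !(raw %in% c("", "NA"))
    if (any(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' of %s",
                   raw[which(bad)[1L]], col, path))
    }
    if (integer) as.integer(out) else out
  }
  vocab <- function(col, allowed) {
    raw <- df[[col]]
    bad <- !(raw %in% c(allowed, "", "NA"))
    if (any(bad)) {
      stop(sprintf("invalid value '%s' in column '%s' of %s (allowed: %s)",
                   raw[which(bad)[1L]], col, path, paste(allowed, collapse = ", ")))
    }
    out <- raw
    out[raw %in% c("", "NA")] <- NA_character_
    out
  }
  out <- data.frame(sample_id = df$sample_id,
                    inflammation_grade = num("inflammation_grade", integer = TRUE),
                    fibrosis_stage = num("fibrosis_stage", integer = TRUE),
                    age_days = num("age_days"),
                    sex = vocab("sex", c("female", "male")),
                    clinical_type = vocab("clinical_type", c("perinatal", "BASM")),
                    cholangitis = num("cholangitis", integer = TRUE),
                    ascites = num("ascites", integer = TRUE),
                    followup_months = num("followup_months"),
                    event = num("event", integer = TRUE),
                    stringsAsFactors = FALSE)
  for (col in c("inflammation_grade", "fibrosis_stage")) {
    v <- out[[col]]
    if (any(!is.na(v) & (v < 0L | v > 3L))) {
      stop(sprintf("column '%s' of %s must lie in 0..3", col, path))
    }
  }
  for (col in c("cholangitis", "ascites", "event")) {
    v <- out[[col]]
    if (any(!is.na(v) & !(v %in% c(0L, 1L)))) {
      stop(sprintf("column '%s' of %s must be 0/1", col, path))
    }
  }
  if (any(!is.na(out$followup_months) & out$followup_months < 0)) {
    stop("'followup_months' must be nonnegative in ", path)
  }
  extra <- setdiff(colnames(df), .sampleTableRequired)
  for (col in extra) out[[col]] <- df[[col]]
  out
}

#' Write a synthetic cohort to plain-text files
#'
#' Emits `expression.tsv` (probes x samples, 15 significant digits),
#' `samples.csv` (the metadata columns [readSampleTable()] expects) and the
#' truth files `truth_samples.csv` (latent group, seed membership) and
#' `truth_probes.csv` (planted probes with signed effects). Round-trips
#' through [readCohort()].
#'
#' @param cohort result of [simulateCohort()] (any SummarizedExperiment with
#'   the same colData layout works).
#' @param directory output directory, created if needed.
#' @return Invisibly, the named vector of file paths.
#' @export
writeCohort <- function(cohort, directory) {
  if (!is(cohort, "SummarizedExperiment")) {
    stop("'cohort' must be a SummarizedExperiment")
  }
  if (ncol(cohort) == 0L) stop("refusing to write an empty cohort (0 samples)")
  if (!dir.exists(directory) &&
      !dir.create(directory, recursive = TRUE, showWarnings = FALSE)) {
    stop("cannot create output directory: ", directory)
  }
  paths <- c(expression = file.path(directory, "expression.tsv"),
             samples = file.path(directory, "samples.csv"),
             truth_samples = file.path(directory, "truth_samples.csv"),
             truth_probes = file.path(directory, "truth_probes.csv"))

  expr <- SummarizedExperiment::assay(cohort)
  mat <- format(expr, digits = 15, trim = TRUE, scientific = FALSE)
  df <- data.frame(probe_id = rownames(expr), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, paths[["expression"]], sep = "\t", quote = FALSE,
              row.names = FALSE)

  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  write.csv(cd[, .sampleTableRequired, drop = FALSE], paths[["samples"]],
            row.names = FALSE, quote = FALSE)

  truthCols <- intersect(c("sample_id", "true_group", "is_seed"), colnames(cd))
  write.csv(cd[, truthCols, drop = FALSE], paths[["truth_samples"]],
            row.names = FALSE, quote = FALSE)

  rd <- as.data.frame(SummarizedExperiment::rowData(cohort))
  if ("planted" %in% colnames(rd)) {
    tp <- data.frame(probe_id = rownames(cohort)[rd$planted],
                     effect = rd$effect[rd$planted])
  } else {
    tp <- data.frame(probe_id = character(0), effect = numeric(0))
  }
  write.csv(tp, paths[["truth_probes"]], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Read a written cohort back into a SummarizedExperiment
#'
#' @param directory directory produced by [writeCohort()].
#' @return A SummarizedExperiment mirroring the written cohort (truth columns
#'   included when the truth files are present).
#' @export
readCohort <- function(directory) {
  expr <- readExpressionTSV(file.path(directory, "expression.tsv"))
  samples <- readSampleTable(file.path(directory, "samples.csv"))
  if (!identical(samples$sample_id, colnames(expr))) {
    stop("sample IDs of expression.tsv and samples.csv disagree in ", directory)
  }
  tsPath <- file.path(directory, "truth_samples.csv")
  if (file.exists(tsPath)) {
    ts <- read.csv(tsPath, stringsAsFactors = FALSE)
    samples <- merge(samples, ts, by = "sample_id", sort = FALSE)
    samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
    if ("is_seed" %in% colnames(samples)) {
      samples$is_seed <- as.logical(samples$is_seed)
    }
  }
  rowData <- S4Vectors::DataFrame(row.names = rownames(expr))
  tpPath <- file.path(directory, "truth_probes.csv")
  if (file.exists(tpPath)) {
    tp <- read.csv(tpPath, stringsAsFactors = FALSE)
    rowData$planted <- rownames(expr) %in% tp$probe_id
    rowData$effect <- 0
    rowData$effect[match(tp$probe_id, rownames(expr))] <- tp$effect
  }
  rownames(samples) <- samples$sample_id
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = expr), rowData = rowData,
    colData = S4Vectors::DataFrame(samples))
}
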