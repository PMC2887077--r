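# End-to-end orchestration: histology grouping -> signature derivation on
# the seed groups -> NSC repeated-CV classification of the remaining
# samples -> clinical association and survival analysis. All stages are
# reproducible from the configured seed and every output is plain text.

#' Pipeline configuration
#'
#' @param expression_tsv path to the expression TSV
#'   (see [readExpressionTSV()]).
#' @param sample_csv path to the sample metadata CSV
#'   (see [readSampleTable()]).
#' @param output_dir directory for the result bundle.
#' @param histology_threshold differential-score threshold for the seed
#'   groups (1 or 2; the study's seed groups use 2).
#' @param fc_threshold,alpha,fdr signature thresholds
#'   (see [deriveSignature()]).
#' @param priors,mk_variant NSC options (see [fitNSC()]).
#' @param delta_grid candidate shrinkage thresholds for [selectDelta()].
#' @param repetitions,folds repeated cross-validation layout (default 10 x 10).
#' @param vote_threshold votes required for assignment (default 6 of 10).
#' @param external_vote_mode `"fold_majority"` or `"full_model"`.
#' @param censor_months administrative censoring horizon (months).
#' @param rng_seed integer seed driving all randomness.
#' @return Validated list of class `"pipeline_config"`.
#' @export
pipelineConfig <- function(expression_tsv, sample_csv, output_dir,
                           histology_threshold = 2, fc_threshold = 2,
                           alpha = 0.05, fdr = 0.05, priors = "empirical",
                           mk_variant = "plus",
                           delta_grid = seq(0, 2, by = 0.25),
                           repetitions = 10, folds = 10, vote_threshold = 6,
                           external_vote_mode = "fold_majority",
                           censor_months = 24, rng_seed = 1) {
  cfg <- list(expression_tsv = expression_tsv, sample_csv = sample_csv,
              output_dir = output_dir,
              histology_threshold = histology_threshold,
              fc_threshold = fc_threshold, alpha = alpha, fdr = fdr,
              priors = priors, mk_variant = mk_variant,
              delta_grid = delta_grid, repetitions = repetitions,
              folds = folds, vote_threshold = vote_threshold,
              external_vote_mode = external_vote_mode,
              censor_months = censor_months, rng_seed = rng_seed)
  if (!cfg$histology_threshold %in% c(1, 2)) {
    stop("'histology_threshold' must be 1 or 2")
  }
  .checkNumericScalar(cfg$fc_threshold, "fc_threshold", lower = 0, strict_lower = TRUE)
  .checkProportion(cfg$alpha, "alpha")
  .checkProportion(cfg$fdr, "fdr")
  if (cfg$vote_threshold < 1 || cfg$vote_threshold > cfg$repetitions) {
    stop("'vote_threshold' must lie in 1..repetitions")
  }
  .checkNumericScalar(cfg$censor_months, "censor_months", lower = 0, strict_lower = TRUE)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a flat YAML file
#'
#' The file holds flat `key: value` pairs with the argument names of
#' [pipelineConfig()]; `delta_grid` may be a YAML list. Keys not present fall
#' back to the defaults.
#'
#' @param path path to the YAML file.
#' @param ... overrides applied on top of the file.
#' @return Validated list of class `"pipeline_config"`.
#' @export
readPipelineConfig <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(pipelineConfig))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$delta_grid)) vals$delta_grid <- as.numeric(unlist(vals$delta_grid))
  do.call(pipelineConfig, vals)
}

#' Run the full molecular staging pipeline
#'
#' Stages, in order: read and cross-check the inputs; assign
#' histology-predominant groups at the configured threshold; derive the
#' expression signature between the seed groups; choose the shrinkage
#' threshold by stratified cross-validation; classify the seed (out-of-fold)
#' and mixed (external) samples by repeated-CV majority voting; test the
#' final molecular groups against clinical covariates and transplant-free
#' survival. Writes `histology_groups.csv`, `signature.tsv`,
#' `filter_trail.json`, `votes.csv`, `association.tsv`, `km_curves.tsv` and
#' `run_log.txt` into the output directory; identical config and seed give
#' identical outputs.
#'
#' @param config a [pipelineConfig()] (or a path to a YAML file for
#'   [readPipelineConfig()]).
#' @return Invisibly, a list with `histology`, `signature`, `delta`,
#'   `votes`, `molecular_groups`, `association`, `km`, and `files`.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  if (!inherits(config, "pipeline_config")) {
    stop("'config' must come from pipelineConfig() or readPipelineConfig()")
  }
  expr <- readExpressionTSV(config$expression_tsv)
  samples <- readSampleTable(config$sample_csv)
  onlyExpr <- setdiff(colnames(expr), samples$sample_id)
  onlyTab <- setdiff(samples$sample_id, colnames(expr))
  if (length(onlyExpr) || length(onlyTab)) {
    stop("sample ID mismatch between expression matrix and sample table; ",
         "only in matrix: [", paste(onlyExpr, collapse = ", "),
         "], only in table: [", paste(onlyTab, collapse = ", "), "]")
  }
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  if (!dir.exists(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE)
  }
  files <- file.path(config$output_dir,
                     c(histology = "histology_groups.csv",
                       signature = "signature.tsv",
                       trail = "filter_trail.json",
                       votes = "votes.csv",
                       association = "association.tsv",
                       km = "km_curves.tsv",
                       log = "run_log.txt"))
  names(files) <- c("histology", "signature", "trail", "votes",
                    "association", "km", "log")
  logLines <- c(sprintf("hepaStage %s", packageVersion("hepaStage")),
                sprintf("rng_seed: %d", as.integer(config$rng_seed)),
                sprintf("histology_threshold: %d", as.integer(config$histology_threshold)))

  # stage 1: histology
  hist <- assignHistologyGroups(
    data.frame(subject_id = samples$sample_id,
               inflammation_grade = samples$inflammation_grade,
               fibrosis_stage = samples$fibrosis_stage),
    threshold = config$histology_threshold)
  counts <- histologyCounts(hist)
  write.csv(as.data.frame(hist), files[["histology"]], row.names = FALSE,
            quote = FALSE)
  logLines <- c(logLines, sprintf(
    "histology groups: inflammation = %d, fibrosis = %d, mixed = %d",
    counts[1L], counts[2L], counts[3L]))

  seedInf <- hist$subject_id[hist$label == "inflammation"]
  seedFib <- hist$subject_id[hist$label == "fibrosis"]
  mixed <- hist$subject_id[hist$label == "mixed"]
  if (length(seedInf) < 2L || length(seedFib) < 2L) {
    stop("each histology seed group needs at least two samples (got ",
         length(seedInf), " inflammation, ", length(seedFib), " fibrosis)")
  }

  # stage 2: signature
  sig <- deriveSignature(expr, inflammation = seedInf, fibrosis = seedFib,
                         fc_threshold = config$fc_threshold,
                         alpha = config$alpha, fdr = config$fdr)
  trail <- filterTrail(sig)
  write.table(signatureTable(sig), files[["signature"]], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(trail, files[["trail"]], auto_unbox = TRUE)
  logLines <- c(logLines, sprintf(
    "filter trail: %d -> %d after fold-change -> %d after FDR",
    trail$n_input, trail$n_after_fc, trail$n_after_fdr))
  probes <- signatureProbes(sig)
  if (length(probes) < 1L) stop("the signature retained no probes; cannot classify")

  # stage 3: NSC with repeated CV majority voting
  seedIds <- c(seedInf, seedFib)
  labels <- factor(rep(c("inflammation", "fibrosis"),
                       c(length(seedInf), length(seedFib))),
                   levels = c("inflammation", "fibrosis"))
  train <- perGeneMedianNormalize(expr)[probes, seedIds, drop = FALSE]
  ext <- perGeneMedianNormalize(expr)[probes, mixed, drop = FALSE]
  folds <- min(config$folds, ncol(train))
  sel <- selectDelta(train, labels, delta_grid = config$delta_grid,
                     folds = folds, seed = config$rng_seed,
                     priors = config$priors, mkVariant = config$mk_variant)
  votes <- repeatedCVClassify(train, labels,
                              external = if (length(mixed)) ext else NULL,
                              repetitions = config$repetitions, folds = folds,
                              delta = sel$delta,
                              voteThreshold = config$vote_threshold,
                              externalVoteMode = config$external_vote_mode,
                              priors = config$priors,
                              mkVariant = config$mk_variant,
                              seed = config$rng_seed)
  vc <- voteCounts(votes)
  write.csv(vc, files[["votes"]], row.names = FALSE, quote = FALSE)
  mol <- assignments(votes)[samples$sample_id]
  logLines <- c(logLines,
                sprintf("selected delta: %g", sel$delta),
                sprintf("molecular groups: inflammation = %d, fibrosis = %d, unclassified = %d (of %d)",
                        sum(mol == "inflammation"), sum(mol == "fibrosis"),
                        sum(mol == "unclassified"), length(mol)))

  # stage 4: clinical association on the classified samples
  assigned <- samples[mol[samples$sample_id] != "unclassified", , drop = FALSE]
  grp <- factor(mol[assigned$sample_id], levels = c("inflammation", "fibrosis"))
  assoc <- .associationReport(assigned, grp, censor_months = config$censor_months)
  write.table(assoc, files[["association"]], sep = "\t", quote = FALSE,
              row.names = FALSE)
  kmTab <- do.call(rbind, lapply(levels(grp), function(g) {
    sel <- grp == g
    if (!any(sel)) return(NULL)
    cbind(group = g, kmEstimate(assigned$followup_months[sel],
                                assigned$event[sel]))
  }))
  write.table(kmTab, files[["km"]], sep = "\t", quote = FALSE, row.names = FALSE)

  writeLines(logLines, files[["log"]])
  invisible(list(histology = hist, signature = sig, delta = sel,
                 votes = votes, molecular_groups = mol, association = assoc,
                 km = kmTab, files = files))
}

# variable/test/statistic/p rows for the molecular-group association stage
.associationReport <- function(samples, group, censor_months = 24) {
  rows <- list()
  addRow <- function(variable, test, statistic, p) {
    rows[[length(rows) + 1L]] <<- data.frame(variable = variable, test = test,
                                             statistic = statistic, p = p,
                                             stringsAsFactors = FALSE)
  }
  cat2x2 <- function(values, variable) {
    keep <- !is.na(values)
    tab <- table(group[keep], factor(values[keep]))
    if (!all(dim(tab) == c(2L, 2L)) || any(rowSums(tab) == 0)) {
      addRow(variable, "fisher_exact", NA_real_, NA_real_)
    } else {
      addRow(variable, "fisher_exact", NA_real_, fisherExact2x2(unclass(tab)))
    }
  }
  cat2x2(samples$sex, "sex")
  cat2x2(samples$clinical_type, "clinical_type")
  cat2x2(samples$cholangitis, "cholangitis")
  cat2x2(samples$ascites, "ascites")
  cat2x2(samples$event, "transplant_death_2y")

  ageInf <- samples$age_days[group == "inflammation" & !is.na(samples$age_days)]
  ageFib <- samples$age_days[group == "fibrosis" & !is.na(samples$age_days)]
  if (length(ageInf) && length(ageFib)) {
    wt <- wilcoxonRankSum(ageInf, ageFib, continuity = TRUE)
    addRow("age_days", "wilcoxon_rank_sum", wt$W, wt$p)
  }

  keep <- !is.na(samples$event)
  tab <- table(group[keep], factor(samples$event[keep], levels = c(1, 0)))
  if (all(dim(tab) == c(2L, 2L)) && all(rowSums(tab) > 0) &&
      all(colSums(tab) > 0)) {
    # odds of transplant/death for fibrosis vs inflammation
    or <- oddsRatioCI(unclass(tab)[c(2L, 1L), ], method = "conditional_exact")
    addRow("transplant_death_2y_odds_ratio", "conditional_exact", or$or, NA_real_)
  }

  lr <- logrankTest(samples$followup_months, samples$event, group)
  addRow("transplant_free_survival", "logrank", lr$chi2, lr$p)

  ageC <- samples$age_days - mean(samples$age_days, na.rm = TRUE)
  ok <- !is.na(ageC) & !is.na(samples$event)
  if (sum(ok) > 4L && length(unique(group[ok])) == 2L) {
    X1 <- cbind(intercept = 1, age = ageC[ok])
    f1 <- logisticFit(samples$event[ok], X1)
    z1 <- f1$coefficients["age"] / f1$se["age"]
    addRow("age_alone", "logistic_wald", unname(z1),
           2 * stats::pnorm(-abs(unname(z1))))
    gnum <- as.integer(group[ok] == "fibrosis")
    X2 <- cbind(intercept = 1, age = ageC[ok], fibrosis = gnum,
                age_x_fibrosis = ageC[ok] * gnum)
    f2 <- tryCatch(logisticFit(samples$event[ok], X2), error = function(e) NULL)
    if (!is.null(f2)) {
      z2 <- f2$coefficients["age_x_fibrosis"] / f2$se["age_x_fibrosis"]
      addRow("group_by_age", "logistic_wald", unname(z2),
             2 * stats::pnorm(-abs(unname(z2))))
    }
  }
  do.call(rbind, rows)
}
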