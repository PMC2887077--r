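#' Per-gene median normalization
#'
#' Subtracts each probe's median across samples on the log2 scale (the
#' division-by-median convention on the linear scale), so every output row
#' has median zero. Idempotent.
#'
#' @param x numeric matrix (probes x samples) of log2 intensities, or a
#'   SummarizedExperiment.
#' @return Matrix of the same shape with row medians equal to zero.
#' @export
perGeneMedianNormalize <- function(x) {
  x <- .asExprMatrix(x)
  x - .rowMedians(x)
}

#' Fold-change filter between two sample groups
#'
#' Retains probe i when `2^|mean_log2(groupA) - mean_log2(groupB)|` is
#' strictly greater than `fc_threshold`, recording the signed log2 fold
#' change (group A minus group B).
#'
#' @param x numeric log2 matrix (probes x samples) or SummarizedExperiment.
#' @param group1,group2 disjoint character vectors of sample IDs; each must
#'   have at least two members. `group1` is conventionally the inflammation
#'   group, `group2` the fibrosis group.
#' @param fc_threshold positive linear-scale fold-change threshold
#'   (default 2; strict inequality, so a fold change of exactly 2 is
#'   excluded).
#' @return `data.frame` with one row per input probe: `probe_id`,
#'   `mean_log2_group1`, `mean_log2_group2`, `log2_fold_change`,
#'   `fold_change`, `retained`.
#' @export
foldChangeFilter <- function(x, group1, group2, fc_threshold = 2) {
  x <- .asExprMatrix(x)
  .checkGroups(x, group1, group2)
  .checkNumericScalar(fc_threshold, "fc_threshold", lower = 0, strict_lower = TRUE)
  m1 <- rowMeans(x[, group1, drop = FALSE])
  m2 <- rowMeans(x[, group2, drop = FALSE])
  lfc <- m1 - m2
  fc <- 2^abs(lfc)
  data.frame(probe_id = rownames(x),
             mean_log2_group1 = m1,
             mean_log2_group2 = m2,
             log2_fold_change = lfc,
             fold_change = fc,
             retained = fc > fc_threshold,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

.checkGroups <- function(x, group1, group2) {
  if (length(group1) < 2L || length(group2) < 2L) {
    stop("each group must contain at least two samples")
  }
  if (length(intersect(group1, group2))) {
    stop("groups overlap: ", paste(intersect(group1, group2), collapse = ", "))
  }
  .checkSampleIds(x, group1, "group1")
  .checkSampleIds(x, group2, "group2")
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t statistic
#' `t = (mean(x) - mean(y)) / sqrt(var(x)/nx + var(y)/ny)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p-value from the
#' Student-t distribution. When both samples have zero variance the test is
#' degenerate: equal means give `t = 0, p = 1`; unequal means give
#' `p = 0` with a warning.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return Named list `t`, `df`, `p`.
#' @export
welchT <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) < 2L || length(y) < 2L) {
    stop("'x' and 'y' must be numeric with at least two observations each")
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("'x' and 'y' must be finite")
  }
  vx <- var(x)
  vy <- var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    warning("degenerate Welch t-test: both samples have zero variance but unequal means")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up q-values: sort p ascending, take `q_i = min_{j >= i} m * p_j / j`
#' capped at 1, and return in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same length and order as `p`.
#' @export
bhAdjust <- function(p) {
  if (!is.numeric(p) || length(p) < 1L) stop("'p' must be a nonempty numeric vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Derive a differential-expression signature between seed groups
#'
#' The study's signature chain: per-gene median normalization, fold-change
#' filter (> `fc_threshold` between the group means), Welch's t-test on the
#' fold-change survivors, Benjamini-Hochberg FDR across the survivors'
#' p-values, retaining probes with `q < fdr` (any such probe also satisfies
#' `p < alpha`). Probes with zero variance in both groups are excluded from
#' testing with a warning. Direction is `"up_in_inflammation"` when the
#' signed log2 fold change (inflammation minus fibrosis) is positive.
#'
#' @param x numeric log2 matrix (probes x samples) or SummarizedExperiment.
#' @param inflammation,fibrosis character vectors of seed-group sample IDs
#'   (typically the threshold-2 histology partition), each of length >= 2.
#' @param fc_threshold linear fold-change threshold, default 2 (strict).
#' @param alpha raw p-value cutoff, default 0.05.
#' @param fdr FDR level, default 0.05 (retention rule `q < fdr`, strict).
#' @param normalize apply [perGeneMedianNormalize()] first (default TRUE).
#' @return A [SignatureResult-class] object.
#' @examples
#' set.seed(1)
#' m <- matrix(rnorm(50 * 8, 7), 50, 8,
#'             dimnames = list(sprintf("p%02d", 1:50), sprintf("s%d", 1:8)))
#' m[1:5, 1:4] <- m[1:5, 1:4] + 2.5  # planted inflammation probes
#' sig <- deriveSignature(m, inflammation = paste0("s", 1:4),
#'                        fibrosis = paste0("s", 5:8))
#' filterTrail(sig)
#' @export
deriveSignature <- function(x, inflammation, fibrosis, fc_threshold = 2,
                            alpha = 0.05, fdr = 0.05, normalize = TRUE) {
  x <- .asExprMatrix(x)
  .checkGroups(x, inflammation, fibrosis)
  .checkProportion(alpha, "alpha")
  .checkProportion(fdr, "fdr")
  if (normalize) x <- perGeneMedianNormalize(x)

  fcf <- foldChangeFilter(x, inflammation, fibrosis, fc_threshold)
  survivors <- fcf[fcf$retained, , drop = FALSE]
  n_input <- nrow(x)
  n_after_fc <- nrow(survivors)

  res <- data.frame(probe_id = character(0),
                    mean_log2_inflammation = numeric(0),
                    mean_log2_fibrosis = numeric(0),
                    log2_fold_change = numeric(0), fold_change = numeric(0),
                    t_stat = numeric(0), df = numeric(0),
                    p_value = numeric(0), q_value = numeric(0),
                    direction = character(0), retained = logical(0),
                    stringsAsFactors = FALSE)
  if (n_after_fc > 0L) {
    xi <- x[survivors$probe_id, inflammation, drop = FALSE]
    xf <- x[survivors$probe_id, fibrosis, drop = FALSE]
    degenerate <- apply(xi, 1L, var) == 0 & apply(xf, 1L, var) == 0
    if (any(degenerate)) {
      warning(sum(degenerate),
              " zero-variance probe(s) excluded from testing: ",
              paste(survivors$probe_id[degenerate], collapse = ", "))
      survivors <- survivors[!degenerate, , drop = FALSE]
      xi <- xi[!degenerate, , drop = FALSE]
      xf <- xf[!degenerate, , drop = FALSE]
    }
    if (nrow(survivors) > 0L) {
      tests <- lapply(seq_len(nrow(survivors)),
                      function(i) welchT(xi[i, ], xf[i, ]))
      pv <- vapply(tests, `[[`, numeric(1), "p")
      qv <- bhAdjust(pv)
      res <- data.frame(probe_id = survivors$probe_id,
                        mean_log2_inflammation = survivors$mean_log2_group1,
                        mean_log2_fibrosis = survivors$mean_log2_group2,
                        log2_fold_change = survivors$log2_fold_change,
                        fold_change = survivors$fold_change,
                        t_stat = vapply(tests, `[[`, numeric(1), "t"),
                        df = vapply(tests, `[[`, numeric(1), "df"),
                        p_value = pv,
                        q_value = qv,
                        direction = ifelse(survivors$log2_fold_change > 0,
                                           "up_in_inflammation", "up_in_fibrosis"),
                        retained = qv < fdr & pv < alpha,
                        stringsAsFactors = FALSE)
      res <- res[order(res$q_value, res$p_value), , drop = FALSE]
      rownames(res) <- NULL
    }
  }

  new("SignatureResult",
      results = res,
      trail = list(n_input = n_input, n_after_fc = n_after_fc,
                   n_after_fdr = sum(res$retained)),
      params = list(fc_threshold = fc_threshold, alpha = alpha, fdr = fdr,
                    normalized = normalize))
}

#' Probe IDs retained in a signature
#'
#' @param object a [SignatureResult-class].
#' @param ... unused.
#' @return Character vector of retained probe IDs (q below the FDR level),
#'   ordered by increasing q.
#' @rdname signatureProbes
#' @export
setMethod("signatureProbes", "SignatureResult", function(object, ...) {
  object@results$probe_id[object@results$retained]
})

#' Filter trail of a signature derivation
#'
#' @param object a [SignatureResult-class].
#' @return Named list `n_input`, `n_after_fc`, `n_after_fdr`.
#' @rdname filterTrail
#' @export
setMethod("filterTrail", "SignatureResult", function(object) object@trail)

#' Per-probe statistics table of a signature
#'
#' @param object a [SignatureResult-class].
#' @param retainedOnly return only the retained probes (default FALSE).
#' @param ... unused.
#' @return `data.frame` of per-probe statistics.
#' @rdname signatureTable
#' @export
setMethod("signatureTable", "SignatureResult",
  function(object, retainedOnly = FALSE, ...) {
    if (retainedOnly) object@results[object@results$retained, , drop = FALSE]
    else object@results
  })

setMethod("show", "SignatureResult", function(object) {
  tr <- object@trail
  cat("SignatureResult\n")
  cat(sprintf("  filter trail: %d probes -> %d after fold-change (> %g) -> %d after FDR (q < %g)\n",
              tr$n_input, tr$n_after_fc, object@params$fc_threshold,
              tr$n_after_fdr, object@params$fdr))
  dirs <- table(object@results$direction[object@results$retained])
  if (length(dirs)) {
    cat("  direction:", paste(sprintf("%s = %d", names(dirs), dirs), collapse = ", "), "\n")
  }
  invisible(NULL)
})
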