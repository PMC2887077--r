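#' SignatureResult: a derived differential-expression signature
#'
#' Holds the per-probe statistics for every probe surviving the fold-change
#' filter (group means on the log2 scale, signed log2 fold change, Welch t,
#' Welch-Satterthwaite df, raw p, Benjamini-Hochberg q, direction) together
#' with the filter trail (number of input probes, probes after the
#' fold-change filter, probes after FDR) and the thresholds used.
#'
#' @slot results `data.frame` with one row per fold-change survivor and
#'   columns `probe_id`, `mean_log2_inflammation`, `mean_log2_fibrosis`,
#'   `log2_fold_change`, `fold_change`, `t_stat`, `df`, `p_value`, `q_value`,
#'   `direction`, `retained`.
#' @slot trail named list: `n_input`, `n_after_fc`, `n_after_fdr`.
#' @slot params named list of thresholds (`fc_threshold`, `alpha`, `fdr`).
#'
#' @seealso [deriveSignature()], [signatureProbes()], [filterTrail()]
#' @export
setClass("SignatureResult",
  representation(results = "data.frame", trail = "list", params = "list"))

setValidity("SignatureResult", function(object) {
  needed <- c("probe_id", "mean_log2_inflammation", "mean_log2_fibrosis",
              "log2_fold_change", "fold_change", "t_stat", "df",
              "p_value", "q_value", "direction", "retained")
  if (!all(needed %in% names(object@results))) {
    return(paste("results must contain columns:", paste(needed, collapse = ", ")))
  }
  tr <- object@trail
  if (!all(c("n_input", "n_after_fc", "n_after_fdr") %in% names(tr))) {
    return("trail must contain n_input, n_after_fc, n_after_fdr")
  }
  if (!(tr$n_after_fdr <= tr$n_after_fc && tr$n_after_fc <= tr$n_input)) {
    return("filter trail must be non-increasing: n_input >= n_after_fc >= n_after_fdr")
  }
  ok <- object@results$q_value >= object@results$p_value - 1e-12
  if (!all(ok | is.na(ok))) return("q values must be >= p values")
  TRUE
})

#' NSCModel: a nearest shrunken centroid classifier
#'
#' Stores everything needed to shrink and predict: probe order, class labels,
#' the overall centroid, class centroids, pooled within-class standard
#' deviations, the fudge constant s0 (median of the pooled SDs), the per-class
#' standardization factor mk, the standardized centroid contrasts d_ik, class
#' priors and the current shrinkage threshold delta. The reconstruction
#' identity `classCentroid_ik = overall_i + mk * (s_i + s0) * d_ik` holds
#' exactly at delta = 0.
#'
#' @slot probeIds ordered probe identifiers.
#' @slot classLabels the two class labels, in prediction tie-break order.
#' @slot nk integer class sizes (named by class).
#' @slot overallCentroid numeric per-probe overall mean.
#' @slot classCentroids numeric matrix, probes x classes.
#' @slot pooledSD numeric per-probe pooled within-class SD.
#' @slot s0 numeric scalar, median of `pooledSD`.
#' @slot mk numeric per-class factor, `sqrt(1/nk + 1/n)` (default variant) or
#'   `sqrt(1/nk - 1/n)`.
#' @slot dik numeric matrix of standardized contrasts, probes x classes.
#' @slot priors numeric class priors summing to one.
#' @slot delta nonnegative soft-threshold applied at prediction time.
#' @slot mkVariant `"plus"` or `"minus"`.
#'
#' @seealso [fitNSC()], [shrinkNSC()], [predictNSC()]
#' @export
setClass("NSCModel",
  representation(probeIds = "character", classLabels = "character",
                 nk = "integer", overallCentroid = "numeric",
                 classCentroids = "matrix", pooledSD = "numeric",
                 s0 = "numeric", mk = "numeric", dik = "matrix",
                 priors = "numeric", delta = "numeric",
                 mkVariant = "character"))

setValidity("NSCModel", function(object) {
  p <- length(object@probeIds)
  K <- length(object@classLabels)
  if (K != 2L) return("exactly two classes are supported")
  if (length(object@overallCentroid) != p) return("overallCentroid length mismatch")
  if (!all(dim(object@classCentroids) == c(p, K))) return("classCentroids dim mismatch")
  if (!all(dim(object@dik) == c(p, K))) return("dik dim mismatch")
  if (length(object@pooledSD) != p) return("pooledSD length mismatch")
  if (any(object@pooledSD < 0)) return("pooledSD must be nonnegative")
  if (abs(sum(object@priors) - 1) > 1e-8) return("priors must sum to 1")
  if (length(object@delta) != 1L || object@delta < 0) return("delta must be a nonnegative scalar")
  if (!object@mkVariant %in% c("plus", "minus")) return("mkVariant must be 'plus' or 'minus'")
  TRUE
})

#' VoteTable: per-sample class votes across cross-validation repetitions
#'
#' One row of votes per sample, one column per repetition. Training samples
#' receive one out-of-fold vote per repetition; external samples receive one
#' vote per repetition (the majority prediction of that repetition's fold
#' models, `NA` when the fold models tie). The final assignment is the class
#' reaching at least `voteThreshold` votes, otherwise `"unclassified"`.
#'
#' @slot sampleIds sample identifiers (training first, then external).
#' @slot votes character matrix, samples x repetitions; `NA` = abstention.
#' @slot classLabels the two class labels.
#' @slot role `"train"` or `"external"` per sample.
#' @slot voteThreshold minimum votes required for assignment (default 6).
#'
#' @seealso [repeatedCVClassify()], [voteCounts()], [assignments()]
#' @export
setClass("VoteTable",
  representation(sampleIds = "character", votes = "matrix",
                 classLabels = "character", role = "character",
                 voteThreshold = "integer"))

setValidity("VoteTable", function(object) {
  if (nrow(object@votes) != length(object@sampleIds)) return("votes rows must match sampleIds")
  if (length(object@role) != length(object@sampleIds)) return("role length mismatch")
  if (!all(object@role %in% c("train", "external"))) return("role must be 'train' or 'external'")
  vals <- object@votes[!is.na(object@votes)]
  if (!all(vals %in% object@classLabels)) return("votes must be class labels or NA")
  if (object@voteThreshold < 1L || object@voteThreshold > ncol(object@votes)) {
    return("voteThreshold must lie in 1..repetitions")
  }
  TRUE
})
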