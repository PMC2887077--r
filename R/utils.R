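# Shared validation helpers. Expression matrices are plain numeric matrices,
# probes x samples, with probe/sample identifiers as dimnames; a
# SummarizedExperiment is accepted anywhere a matrix is and its first assay
# is used.

`%||%` <- function(a, b) if (is.null(a)) b else a

.asExprMatrix <- function(x, arg = "x") {
  if (is(x, "SummarizedExperiment")) {
    x <- SummarizedExperiment::assay(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix (probes x samples) or a SummarizedExperiment", arg))
  }
  if (nrow(x) < 1L || ncol(x) < 1L) {
    stop(sprintf("'%s' must have at least one probe and one sample", arg))
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop(sprintf("'%s' must carry probe IDs as rownames and sample IDs as colnames", arg))
  }
  if (anyDuplicated(rownames(x))) {
    stop(sprintf("duplicate probe IDs in '%s': %s", arg,
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  }
  if (anyDuplicated(colnames(x))) {
    stop(sprintf("duplicate sample IDs in '%s': %s", arg,
                 paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", ")))
  }
  if (!all(is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", arg))
  }
  x
}

.checkSampleIds <- function(x, ids, arg) {
  missing <- setdiff(ids, colnames(x))
  if (length(missing)) {
    stop(sprintf("sample IDs in '%s' not present in the expression matrix: %s",
                 arg, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

.checkNumericScalar <- function(value, field, lower = -Inf, upper = Inf,
                                strict_lower = FALSE) {
  if (!is.numeric(value) || length(value) != 1L || !is.finite(value)) {
    stop(sprintf("'%s' must be a single finite number", field))
  }
  if (strict_lower && value <= lower) {
    stop(sprintf("'%s' must be > %s", field, lower))
  }
  if (!strict_lower && value < lower) {
    stop(sprintf("'%s' must be >= %s", field, lower))
  }
  if (value > upper) {
    stop(sprintf("'%s' must be <= %s", field, upper))
  }
  invisible(value)
}

.checkProportion <- function(value, field) {
  .checkNumericScalar(value, field, lower = 0, upper = 1)
}

# row medians without extra dependencies; x already validated
.rowMedians <- function(x) {
  apply(x, 1L, median)
}
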