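# Nearest shrunken centroid (PAM-style) classification restricted to the
# signature probes. Two classes. The standardized centroid contrast for
# probe i and class k is
#   d_ik = (xbar_ik - xbar_i) / (m_k * (s_i + s0)),
# with s_i the pooled within-class SD, s0 = median(s_i), and
# m_k = sqrt(1/n_k + 1/n) (default; sqrt(1/n_k - 1/n) is the variance-exact
# variant selectable with mkVariant = "minus"). Shrinkage soft-thresholds
# d_ik by delta; prediction minimizes the standardized squared distance to
# the shrunken centroid minus twice the log prior.

#' Fit a nearest shrunken centroid model
#'
#' Computes class centroids, the overall centroid, pooled within-class
#' standard deviations `s_i` with `s_i^2 = (1/(n-K)) * sum_k sum_{j in C_k}
#' (x_ij - xbar_ik)^2`, the fudge constant `s0 = median(s_i)`, and the
#' standardized contrasts `d_ik`. The reconstruction identity
#' `xbar_ik = xbar_i + m_k (s_i + s0) d_ik` holds exactly.
#'
#' @param x numeric log2 matrix (probes x samples), typically restricted to
#'   signature probes; or a SummarizedExperiment.
#' @param labels class label per sample (character or factor, two classes,
#'   each with at least two samples). The class order of the model follows
#'   `levels(factor(labels))` unless `labels` is already a factor.
#' @param priors `"empirical"` (class proportions, default), `"uniform"`, or
#'   a numeric vector of two probabilities summing to one.
#' @param mkVariant `"plus"` for `m_k = sqrt(1/n_k + 1/n)` (default) or
#'   `"minus"` for `sqrt(1/n_k - 1/n)`.
#' @param s0 override for the fudge constant (default: median of the pooled
#'   SDs). Setting `s0 = 0` gives the plain standardized-centroid limit.
#' @param delta initial shrinkage threshold (default 0, no shrinkage).
#' @return An [NSCModel-class] object.
#' @examples
#' x <- matrix(c(1, 3, 5, 7), 1, 4,
#'             dimnames = list("p1", c("a1", "a2", "b1", "b2")))
#' fitNSC(x, c("A", "A", "B", "B"))
#' @export
fitNSC <- function(x, labels, priors = "empirical",
                   mkVariant = c("plus", "minus"), s0 = NULL, delta = 0) {
  x <- .asExprMatrix(x)
  mkVariant <- match.arg(mkVariant)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x)) {
    stop("'labels' must have one entry per sample (column) of 'x'")
  }
  classes <- levels(droplevels(labels))
  if (length(classes) != 2L) stop("exactly two classes are required")
  nk <- table(labels)[classes]
  if (any(nk < 2L)) {
    stop("each class needs at least two samples; got ",
         paste(sprintf("%s = %d", classes, nk), collapse = ", "))
  }
  n <- ncol(x)
  K <- 2L

  classCentroids <- matrix(0, nrow(x), K, dimnames = list(rownames(x), classes))
  withinSS <- numeric(nrow(x))
  for (cl in classes) {
    xc <- x[, labels == cl, drop = FALSE]
    classCentroids[, cl] <- rowMeans(xc)
    withinSS <- withinSS + rowSums((xc - classCentroids[, cl])^2)
  }
  overall <- rowMeans(x)
  si <- sqrt(withinSS / (n - K))
  s0v <- if (is.null(s0)) median(si) else .checkNumericScalar(s0, "s0", lower = 0)
  if (all(si + s0v == 0)) {
    stop("all probes have zero pooled variance (and s0 = 0); cannot standardize centroids")
  }

  mk <- switch(mkVariant,
               plus = sqrt(1 / as.numeric(nk) + 1 / n),
               minus = sqrt(pmax(1 / as.numeric(nk) - 1 / n, 0)))
  names(mk) <- classes
  if (any(mk == 0)) stop("mk is zero for a class; use mkVariant = 'plus'")

  denom <- (si + s0v) %o% mk  # probes x classes
  if (any(denom == 0)) {
    stop("zero standardization denominator (s_i + s0 = 0) for some probe")
  }
  dik <- (classCentroids - overall) / denom

  pri <- .resolvePriors(priors, nk, classes)

  new("NSCModel",
      probeIds = rownames(x), classLabels = classes,
      nk = setNames(as.integer(nk), classes),
      overallCentroid = setNames(overall, rownames(x)),
      classCentroids = classCentroids, pooledSD = setNames(si, rownames(x)),
      s0 = s0v, mk = mk, dik = dik, priors = pri,
      delta = .checkNumericScalar(delta, "delta", lower = 0),
      mkVariant = mkVariant)
}

.resolvePriors <- function(priors, nk, classes) {
  if (is.character(priors)) {
    priors <- match.arg(priors, c("empirical", "uniform"))
    pri <- if (priors == "empirical") as.numeric(nk) / sum(nk) else rep(0.5, 2L)
  } else {
    if (!is.numeric(priors) || length(priors) != 2L || any(priors <= 0) ||
        abs(sum(priors) - 1) > 1e-8) {
      stop("'priors' must be 'empirical', 'uniform', or two positive numbers summing to 1")
    }
    pri <- as.numeric(priors)
  }
  setNames(pri, classes)
}

.softThreshold <- function(d, delta) sign(d) * pmax(abs(d) - delta, 0)

#' Set the shrinkage threshold of an NSC model
#'
#' Returns the model with `delta` updated; the shrunken contrasts
#' `d'_ik = sign(d_ik) * max(|d_ik| - delta, 0)` and shrunken centroids
#' `xbar_i + m_k (s_i + s0) d'_ik` are derived on demand by
#' [shrunkenContrasts()], [shrunkenCentroids()] and [predictNSC()].
#'
#' @param model an [NSCModel-class].
#' @param delta nonnegative shrinkage threshold.
#' @return The model with the new `delta`.
#' @export
shrinkNSC <- function(model, delta) {
  stopifnot(is(model, "NSCModel"))
  model@delta <- .checkNumericScalar(delta, "delta", lower = 0)
  model
}

#' Shrunken standardized contrasts of an NSC model
#'
#' @param model an [NSCModel-class].
#' @return Matrix of soft-thresholded `d'_ik`, probes x classes.
#' @export
shrunkenContrasts <- function(model) {
  stopifnot(is(model, "NSCModel"))
  .softThreshold(model@dik, model@delta)
}

#' Shrunken class centroids of an NSC model
#'
#' @param model an [NSCModel-class].
#' @return Matrix of shrunken centroids, probes x classes; equals the fitted
#'   class centroids at `delta = 0` and collapses to the overall centroid at
#'   full shrinkage.
#' @export
shrunkenCentroids <- function(model) {
  stopifnot(is(model, "NSCModel"))
  denom <- (model@pooledSD + model@s0) %o% model@mk
  model@overallCentroid + denom * shrunkenContrasts(model)
}

#' Probes surviving shrinkage
#'
#' @param object an [NSCModel-class].
#' @return Character vector of probes with a nonzero shrunken contrast in at
#'   least one class; nonincreasing in `delta`.
#' @rdname survivingProbes
#' @export
setMethod("survivingProbes", "NSCModel", function(object) {
  ds <- shrunkenContrasts(object)
  object@probeIds[rowSums(abs(ds) > 0) > 0]
})

#' Predict classes with a nearest shrunken centroid model
#'
#' Discriminant score for class k:
#' `delta_k(x) = sum_i (x_i - xbar'_ik)^2 / (s_i + s0)^2 - 2 log pi_k`;
#' the predicted label minimizes the score, and class probabilities are
#' `exp(-delta_k/2)` normalized after subtracting the minimum score for
#' numerical stability. Exact score ties are broken by class order with a
#' warning.
#'
#' @param model an [NSCModel-class].
#' @param newdata numeric vector over the model probes, or a matrix
#'   (probes x samples) / SummarizedExperiment whose rows cover the model
#'   probes (aligned by rowname when present).
#' @return List with `class` (character vector), `probabilities`
#'   (samples x classes) and `scores` (samples x classes).
#' @export
predictNSC <- function(model, newdata) {
  stopifnot(is(model, "NSCModel"))
  if (is(newdata, "SummarizedExperiment")) newdata <- SummarizedExperiment::assay(newdata)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, ncol = 1L,
                      dimnames = list(names(newdata), "sample1"))
  }
  if (!is.null(rownames(newdata))) {
    missing <- setdiff(model@probeIds, rownames(newdata))
    if (length(missing)) {
      stop("newdata lacks model probes: ", paste(missing, collapse = ", "))
    }
    newdata <- newdata[model@probeIds, , drop = FALSE]
  } else if (nrow(newdata) != length(model@probeIds)) {
    stop("newdata has ", nrow(newdata), " rows but the model has ",
         length(model@probeIds), " probes")
  }
  if (!all(is.finite(newdata))) stop("newdata must be finite")

  cent <- shrunkenCentroids(model)
  w <- 1 / (model@pooledSD + model@s0)^2
  scores <- vapply(model@classLabels, function(cl) {
    colSums(w * (newdata - cent[, cl])^2) - 2 * log(model@priors[cl])
  }, numeric(ncol(newdata)))
  if (ncol(newdata) == 1L) scores <- matrix(scores, nrow = 1L,
                                            dimnames = list(colnames(newdata),
                                                            model@classLabels))
  ties <- abs(scores[, 1L] - scores[, 2L]) == 0
  if (any(ties)) {
    warning(sum(ties), " tied discriminant score(s); broken by class order (",
            model@classLabels[1L], " first)")
  }
  lab <- model@classLabels[max.col(-scores, ties.method = "first")]
  shifted <- scores - apply(scores, 1L, min)
  pk <- exp(-shifted / 2)
  pk <- pk / rowSums(pk)
  rownames(scores) <- rownames(pk) <- colnames(newdata)
  list(class = setNames(lab, colnames(newdata)), probabilities = pk,
       scores = scores)
}

#' @describeIn fitNSC `predict` method dispatching to [predictNSC()].
#' @param object an [NSCModel-class].
#' @param newdata samples to classify.
#' @param ... unused.
#' @export
setMethod("predict", "NSCModel", function(object, newdata, ...) {
  predictNSC(object, newdata)
})

setMethod("show", "NSCModel", function(object) {
  cat("NSCModel:", length(object@probeIds), "probes,",
      paste(sprintf("%s (n=%d)", object@classLabels, object@nk), collapse = " vs "),
      "\n")
  cat(sprintf("  s0 = %.4g, delta = %.4g, surviving probes = %d, priors = %s, mk variant = %s\n",
              object@s0, object@delta, length(survivingProbes(object)),
              paste(sprintf("%.3f", object@priors), collapse = "/"),
              object@mkVariant))
  invisible(NULL)
})

# Stratified fold assignment: shuffle within class, then deal samples
# round-robin across folds, continuing the cycle across classes so fold
# sizes stay balanced even when classes are small (e.g. 9 + 5 into 10
# folds gives folds of 1-2 samples).
.stratifiedFolds <- function(labels, k) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2L || k > n) stop("'folds' must lie in 2..n_train")
  fold <- integer(n)
  cursor <- 0L
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((cursor + seq_along(idx) - 1L) %% k) + 1L
    cursor <- cursor + length(idx)
  }
  fold
}

#' Choose the shrinkage threshold by stratified cross-validated error
#'
#' Computes the stratified k-fold misclassification error for each candidate
#' delta and returns the largest delta attaining the minimum (preferring
#' sparser models on ties). With the study's seed set the minimum occurs at
#' `delta = 0`, i.e. removing any probe increases the cross-validated error.
#'
#' @param x numeric log2 matrix (probes x samples) or SummarizedExperiment.
#' @param labels class per sample (two classes).
#' @param delta_grid nonnegative candidate thresholds; must include 0.
#' @param folds number of folds (default 10).
#' @param seed integer seed controlling the fold partition.
#' @param priors,mkVariant passed to [fitNSC()].
#' @return List with `delta` (the chosen threshold), `cv_error`
#'   (`data.frame` of delta and error) and `folds` (fold id per sample).
#' @export
selectDelta <- function(x, labels, delta_grid = seq(0, 2, by = 0.25),
                        folds = 10, seed = 1, priors = "empirical",
                        mkVariant = "plus") {
  x <- .asExprMatrix(x)
  if (length(delta_grid) < 1L) stop("'delta_grid' must be nonempty")
  if (any(delta_grid < 0)) stop("'delta_grid' must be nonnegative")
  if (!any(delta_grid == 0)) stop("'delta_grid' must include 0")
  delta_grid <- sort(unique(delta_grid))
  labels <- as.factor(labels)

  set.seed(as.integer(seed))
  fold <- .stratifiedFolds(labels, folds)
  errors <- matrix(0, nrow = length(delta_grid), ncol = 1L)
  for (f in sort(unique(fold))) {
    train <- fold != f
    fit <- fitNSC(x[, train, drop = FALSE], labels[train],
                  priors = priors, mkVariant = mkVariant)
    for (gi in seq_along(delta_grid)) {
      pred <- suppressWarnings(
        predictNSC(shrinkNSC(fit, delta_grid[gi]), x[, !train, drop = FALSE]))
      errors[gi] <- errors[gi] + sum(pred$class != as.character(labels)[!train])
    }
  }
  err <- as.numeric(errors) / length(labels)
  best <- max(delta_grid[err == min(err)])
  list(delta = best,
       cv_error = data.frame(delta = delta_grid, error = err),
       folds = fold)
}

#' Repeated cross-validated classification with majority voting
#'
#' Runs `repetitions` independent stratified `folds`-fold partitions of the
#' training samples. In each repetition every training sample receives one
#' out-of-fold vote (the prediction of the model fit on the other folds) and
#' every external sample receives one vote: by default the majority
#' prediction over that repetition's fold models (a tie makes the repetition
#' abstain); with `externalVoteMode = "full_model"` the vote of a single
#' model fit on all training samples. A sample is assigned the class that
#' collects at least `voteThreshold` of the `repetitions` votes, otherwise it
#' stays `"unclassified"` -- the six-of-ten rule at the defaults.
#'
#' @param x training matrix (probes x samples) or SummarizedExperiment,
#'   restricted to the signature probes.
#' @param labels training class per sample (two classes, each >= 2 samples).
#' @param external optional matrix of unlabeled samples over the same probes.
#' @param repetitions number of repeated partitions (default 10).
#' @param folds folds per repetition (default 10; must not exceed the number
#'   of training samples).
#' @param delta shrinkage threshold used for every fold model (default 0).
#' @param voteThreshold votes required for assignment (default 6).
#' @param externalVoteMode `"fold_majority"` (default) or `"full_model"`.
#' @param priors,mkVariant passed to [fitNSC()].
#' @param seed integer seed; all partition randomness derives from it.
#' @return A [VoteTable-class] covering training then external samples.
#' @export
repeatedCVClassify <- function(x, labels, external = NULL, repetitions = 10,
                               folds = 10, delta = 0, voteThreshold = 6,
                               externalVoteMode = c("fold_majority", "full_model"),
                               priors = "empirical", mkVariant = "plus",
                               seed = 1) {
  x <- .asExprMatrix(x)
  externalVoteMode <- match.arg(externalVoteMode)
  labels <- as.factor(labels)
  if (length(labels) != ncol(x)) stop("'labels' must match the training samples")
  classes <- levels(droplevels(labels))
  if (length(classes) != 2L) stop("training data must contain both classes")
  if (folds > ncol(x)) stop("'folds' exceeds the number of training samples")
  repetitions <- as.integer(repetitions)
  voteThreshold <- as.integer(voteThreshold)
  if (voteThreshold < 1L || voteThreshold > repetitions) {
    stop("'voteThreshold' must lie in 1..repetitions")
  }
  if (!is.null(external)) {
    if (is(external, "SummarizedExperiment")) external <- SummarizedExperiment::assay(external)
    if (is.null(dim(external))) external <- matrix(external, ncol = 1L,
                                                   dimnames = list(names(external), "external1"))
    if (!is.null(rownames(external))) {
      external <- external[rownames(x), , drop = FALSE]
    }
  }
  nExt <- if (is.null(external)) 0L else ncol(external)

  set.seed(as.integer(seed))
  votesTrain <- matrix(NA_character_, ncol(x), repetitions,
                       dimnames = list(colnames(x), NULL))
  votesExt <- matrix(NA_character_, nExt, repetitions,
                     dimnames = list(colnames(external), NULL))
  for (r in seq_len(repetitions)) {
    fold <- .stratifiedFolds(labels, folds)
    extPreds <- matrix(NA_character_, nExt, length(unique(fold)))
    for (fi in seq_along(sort(unique(fold)))) {
      f <- sort(unique(fold))[fi]
      train <- fold != f
      fit <- shrinkNSC(fitNSC(x[, train, drop = FALSE], labels[train],
                              priors = priors, mkVariant = mkVariant), delta)
      heldout <- which(!train)
      pred <- suppressWarnings(predictNSC(fit, x[, heldout, drop = FALSE]))
      votesTrain[heldout, r] <- pred$class
      if (nExt > 0L && externalVoteMode == "fold_majority") {
        extPreds[, fi] <- suppressWarnings(predictNSC(fit, external))$class
      }
    }
    if (nExt > 0L) {
      if (externalVoteMode == "fold_majority") {
        votesExt[, r] <- apply(extPreds, 1L, function(v) {
          tab <- table(factor(v, levels = classes))
          if (tab[1L] == tab[2L]) NA_character_ else names(which.max(tab))
        })
      } else {
        full <- shrinkNSC(fitNSC(x, labels, priors = priors,
                                 mkVariant = mkVariant), delta)
        votesExt[, r] <- suppressWarnings(predictNSC(full, external))$class
      }
    }
  }

  new("VoteTable",
      sampleIds = c(colnames(x), colnames(external)),
      votes = rbind(votesTrain, votesExt),
      classLabels = classes,
      role = c(rep("train", ncol(x)), rep("external", nExt)),
      voteThreshold = voteThreshold)
}

#' Vote counts and final assignments
#'
#' @param object a [VoteTable-class].
#' @return `data.frame` with `sample_id`, `role`, one `n_votes_<class>`
#'   column per class, `n_abstain`, and `assignment` (`"unclassified"` when
#'   no class reaches the vote threshold).
#' @rdname voteCounts
#' @export
setMethod("voteCounts", "VoteTable", function(object) {
  cls <- object@classLabels
  counts <- t(apply(object@votes, 1L, function(v)
    table(factor(v, levels = cls))))
  nAbstain <- ncol(object@votes) - rowSums(counts)
  top <- max.col(counts, ties.method = "first")
  assignment <- ifelse(counts[cbind(seq_len(nrow(counts)), top)] >= object@voteThreshold,
                       cls[top], "unclassified")
  out <- data.frame(sample_id = object@sampleIds, role = object@role,
                    stringsAsFactors = FALSE)
  for (k in seq_along(cls)) out[[paste0("n_votes_", cls[k])]] <- as.integer(counts[, k])
  out$n_abstain <- as.integer(nAbstain)
  out$assignment <- assignment
  out
})

#' Final class assignments of a vote table
#'
#' @param object a [VoteTable-class].
#' @return Named character vector, one of the class labels or
#'   `"unclassified"` per sample.
#' @rdname assignments
#' @export
setMethod("assignments", "VoteTable", function(object) {
  vc <- voteCounts(object)
  setNames(vc$assignment, vc$sample_id)
})

setMethod("show", "VoteTable", function(object) {
  vc <- voteCounts(object)
  cat("VoteTable:", nrow(vc), "samples (",
      sum(vc$role == "train"), "train,", sum(vc$role == "external"),
      "external ),", ncol(object@votes), "repetitions, >=",
      object@voteThreshold, "votes to assign\n")
  print(table(assignment = vc$assignment, role = vc$role))
  invisible(NULL)
})
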