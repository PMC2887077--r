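# Association of molecular groups with clinical covariates and outcome.
# Standard tests are delegated to base R / survival behind a validated
# surface; group conventions follow the cohort tables (rows = group,
# columns = outcome).

.as2x2 <- function(x) {
  if (is.matrix(x)) {
    if (!all(dim(x) == c(2L, 2L))) stop("table must be 2x2")
    tab <- x
  } else if (is.numeric(x) && length(x) == 4L) {
    # cells (a, b, c, d) filled row-wise: rows = group, cols = outcome
    tab <- matrix(x, 2L, 2L, byrow = TRUE)
  } else {
    stop("table must be a 2x2 matrix or the four cell counts (a, b, c, d)")
  }
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab))) {
    stop("cell counts must be nonnegative integers")
  }
  if (sum(tab) < 1) stop("table total must be positive")
  storage.mode(tab) <- "integer"
  tab
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value: the sum of hypergeometric probabilities, over all
#' tables with the observed margins, that do not exceed the probability of
#' the observed table.
#'
#' @param table 2x2 integer matrix (rows = group, columns = outcome).
#' @return Two-sided p-value.
#' @examples
#' fisherExact2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE))  # 1/3
#' @export
fisherExact2x2 <- function(table) {
  tab <- .as2x2(table)
  fisher.test(tab)$p.value
}

#' Odds ratio of a 2x2 table with a 95% confidence interval
#'
#' `method = "conditional_exact"` (default) inverts the noncentral
#' hypergeometric likelihood (conditional maximum-likelihood estimate and
#' exact interval); `method = "woolf_haldane"` uses the sample odds ratio
#' `ad/bc` with the Woolf log-normal interval, adding 0.5 to every cell
#' (Haldane correction) when any cell is zero.
#'
#' @param table 2x2 integer matrix (rows = group, columns = outcome).
#' @param method `"conditional_exact"` or `"woolf_haldane"`.
#' @param conf_level confidence level, default 0.95.
#' @return List `or`, `ci_low`, `ci_high`, `method`, `corrected` (whether the
#'   Haldane correction was applied).
#' @export
oddsRatioCI <- function(table, method = c("conditional_exact", "woolf_haldane"),
                        conf_level = 0.95) {
  tab <- .as2x2(table)
  method <- match.arg(method)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("odds ratio undefined: a row or column of the table is entirely zero")
  }
  if (method == "conditional_exact") {
    ft <- fisher.test(tab, conf.level = conf_level)
    return(list(or = unname(ft$estimate), ci_low = ft$conf.int[1L],
                ci_high = ft$conf.int[2L], method = method, corrected = FALSE))
  }
  corrected <- any(tab == 0)
  tc <- tab + if (corrected) 0.5 else 0
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  se <- sqrt(sum(1 / tc))
  list(or = or, ci_low = or * exp(-z * se), ci_high = or * exp(z * se),
       method = method, corrected = corrected)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks for ties; exact enumeration when the pooled size is at most 12
#' and there are no ties, otherwise the normal approximation with
#' tie-corrected variance and optional continuity correction (the study's
#' age comparisons use the continuity-corrected test).
#'
#' @param x,y nonempty numeric vectors.
#' @param continuity apply the +/- 0.5 continuity correction in the normal
#'   approximation (default TRUE; ignored when the exact test is used).
#' @return List `W` (rank-sum statistic of `x`), `p` (two-sided), `exact`.
#' @export
wilcoxonRankSum <- function(x, y, continuity = TRUE) {
  if (!is.numeric(x) || !is.numeric(y) || !length(x) || !length(y)) {
    stop("'x' and 'y' must be nonempty numeric vectors")
  }
  exact <- (length(x) + length(y) <= 12L) && !anyDuplicated(c(x, y))
  wt <- wilcox.test(x, y, exact = exact, correct = continuity)
  list(W = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Kruskal-Wallis one-way analysis of variance on ranks
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom. When every observation is identical the statistic is defined as
#' zero with p = 1.
#'
#' @param groups list of two or more nonempty numeric vectors.
#' @return List `H`, `df`, `p`.
#' @export
kruskalWallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("'groups' must be a list of at least two sample vectors")
  }
  if (any(!vapply(groups, length, integer(1)))) stop("each group must be nonempty")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) stop("need at least three observations in total")
  if (length(unique(pooled)) == 1L) {
    return(list(H = 0, df = length(groups) - 1L, p = 1))
  }
  kt <- kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Gaussian kernel density of ages
#'
#' Gaussian KDE with the Silverman rule-of-thumb bandwidth
#' `0.9 * min(sd, IQR/1.34) * n^(-1/5)` (or an explicit positive bandwidth),
#' evaluated on a grid spanning four bandwidths beyond the data range; the
#' density integrates to one within 1e-3 on that grid.
#'
#' @param ages numeric vector (days); at least two distinct values are
#'   required for the Silverman bandwidth.
#' @param bandwidth `"silverman"` (default) or a positive number.
#' @param gridSize number of grid points (default 512).
#' @return List `x` (grid), `density`, `bandwidth`, `n`.
#' @export
ageDensity <- function(ages, bandwidth = "silverman", gridSize = 512) {
  if (!is.numeric(ages) || length(ages) < 1L || !all(is.finite(ages))) {
    stop("'ages' must be a finite numeric vector")
  }
  if (is.character(bandwidth)) {
    bandwidth <- match.arg(bandwidth, "silverman")
    if (length(unique(ages)) < 2L) {
      stop("the Silverman bandwidth needs at least two distinct values")
    }
    h <- bw.nrd0(ages)
  } else {
    h <- .checkNumericScalar(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  }
  d <- density(ages, bw = h, kernel = "gaussian",
               from = min(ages) - 4 * h, to = max(ages) + 4 * h, n = gridSize)
  list(x = d$x, density = d$y, bandwidth = h, n = length(ages))
}

#' Compare the centers of two age distributions
#'
#' Default: Wilcoxon rank-sum with continuity correction (the test the study
#' pairs with its kernel-density age comparison). Option: a seeded
#' permutation test on the difference of medians.
#'
#' @param x,y nonempty numeric vectors.
#' @param method `"wilcoxon"` (default) or `"permutation"`.
#' @param nPermutations permutations for the permutation test (default
#'   10000).
#' @param seed integer seed for the permutation test.
#' @return List `p`, `method`, `statistic` (rank-sum W or observed median
#'   difference).
#' @export
compareAgeCenters <- function(x, y, method = c("wilcoxon", "permutation"),
                              nPermutations = 10000, seed = 1) {
  method <- match.arg(method)
  if (method == "wilcoxon") {
    wt <- wilcoxonRankSum(x, y, continuity = TRUE)
    return(list(p = wt$p, method = method, statistic = wt$W))
  }
  if (!length(x) || !length(y)) stop("'x' and 'y' must be nonempty")
  obs <- median(x) - median(y)
  pooled <- c(x, y)
  nx <- length(x)
  set.seed(as.integer(seed))
  perm <- replicate(nPermutations, {
    idx <- sample.int(length(pooled), nx)
    median(pooled[idx]) - median(pooled[-idx])
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + nPermutations)
  list(p = p, method = method, statistic = obs)
}

.checkSurvival <- function(time, event) {
  if (!is.numeric(time) || !length(time) || anyNA(time) || any(time < 0)) {
    stop("'time' must be nonnegative")
  }
  if (length(event) != length(time) || !all(event %in% c(0, 1))) {
    stop("'event' must be 0/1 with one entry per time")
  }
  invisible(TRUE)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` with censored subjects tied to an
#' event time still counted at risk for that event (the standard
#' right-continuous convention).
#'
#' @param time follow-up times in months, nonnegative.
#' @param event 1 = transplant or death, 0 = censored.
#' @return `data.frame` with one row per observed time: `time`, `n_risk`,
#'   `n_event`, `n_censor`, `survival`; `S(0) = 1` implicitly.
#' @export
kmEstimate <- function(time, event) {
  .checkSurvival(time, event)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             n_censor = sf$n.censor, survival = sf$surv)
}

#' Survival probability of a Kaplan-Meier curve at given times
#'
#' @param curve result of [kmEstimate()].
#' @param t times at which to evaluate the step function.
#' @return Numeric vector of survival probabilities.
#' @export
kmSurvivalAt <- function(curve, t) {
  vapply(t, function(ti) {
    past <- curve$time <= ti
    if (!any(past)) 1 else curve$survival[max(which(past))]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' At each event time the observed minus expected events in the first group
#' are accumulated with the hypergeometric variance;
#' `chi2 = (sum(O - E))^2 / sum(V)` referred to chi-square with one degree of
#' freedom. Also reports the O/E-based log hazard-ratio estimate
#' `log((O1/E1)/(O2/E2))` of the first group versus the second.
#'
#' @param time follow-up times (months).
#' @param event 1 = event, 0 = censored.
#' @param group two-level factor or character vector.
#' @return List `chi2`, `df`, `p`, `observed`, `expected` (per group, in
#'   factor-level order), `log_hazard_ratio`.
#' @export
logrankTest <- function(time, event, group) {
  .checkSurvival(time, event)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) stop("'group' must have exactly two levels")
  if (length(group) != length(time)) stop("'group' must match 'time'")
  if (sum(event) == 0) {
    warning("no events in either group; log-rank chi2 = 0, p = 1")
    return(list(chi2 = 0, df = 1L, p = 1,
                observed = setNames(c(0, 0), levels(group)),
                expected = setNames(c(NA_real_, NA_real_), levels(group)),
                log_hazard_ratio = NA_real_))
  }
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  chi2 <- unname(sd$chisq)
  obs <- setNames(as.numeric(sd$obs), levels(group))
  exp <- setNames(as.numeric(sd$exp), levels(group))
  lhr <- if (all(obs > 0) && all(exp > 0)) {
    log((obs[1L] / exp[1L]) / (obs[2L] / exp[2L]))
  } else NA_real_
  list(chi2 = chi2, df = 1L, p = pchisq(chi2, df = 1, lower.tail = FALSE),
       observed = obs, expected = exp, log_hazard_ratio = unname(lhr))
}

#' Binary logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood fit of a binary outcome on a design matrix that
#' already includes its intercept column. Rank-deficient designs are
#' rejected naming the offending column; complete separation (fitted
#' probabilities collapsing onto the outcome) is flagged and reported as
#' non-converged.
#'
#' @param outcome 0/1 vector.
#' @param design numeric design matrix with named columns, including the
#'   intercept; `nrow(design)` must exceed `ncol(design)`.
#' @return List `coefficients`, `se` (both named), `converged`, `separated`,
#'   `fitted`.
#' @export
logisticFit <- function(outcome, design) {
  if (!all(outcome %in% c(0, 1))) stop("'outcome' must be 0/1")
  if (!is.matrix(design) || !is.numeric(design)) stop("'design' must be a numeric matrix")
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  if (length(outcome) != nrow(design)) stop("'outcome' must match the design rows")
  if (length(outcome) <= ncol(design)) {
    stop("need more observations than covariates")
  }
  qrd <- qr(design)
  if (qrd$rank < ncol(design)) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):ncol(design)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- suppressWarnings(
    glm(outcome ~ 0 + design, family = binomial(),
        control = glm.control(epsilon = 1e-10, maxit = 50)))
  coefs <- setNames(unname(coef(fit)), colnames(design))
  se <- setNames(unname(sqrt(diag(vcov(fit)))), colnames(design))
  fitted <- fit$fitted.values
  eps <- 1e-4
  separated <- all(fitted[outcome == 1] > 1 - eps) &&
    all(fitted[outcome == 0] < eps)
  list(coefficients = coefs, se = se,
       converged = fit$converged && !separated,
       separated = separated, fitted = unname(fitted))
}
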