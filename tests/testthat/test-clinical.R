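# enumeration oracle for the two-sided Fisher p of a 2x2 table
fisherEnumOracle <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  pr <- dhyper(support, m, n2, k)
  pObs <- dhyper(a, m, n2, k)
  sum(pr[pr <= pObs * (1 + 1e-7)])
}

# hand-walked log-rank: O/E/V over the pooled event times
logrankOracle <- function(time, event, group) {
  g1 <- levels(factor(group))[1]
  U <- 0; V <- 0
  for (t in sort(unique(time[event == 1]))) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    U <- U + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chi2 <- U^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

test_that("Fisher's exact two-sided p matches full enumeration", {
  expect_equal(fisherExact2x2(matrix(c(2, 0, 0, 2), 2, byrow = TRUE)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisherExact2x2(matrix(c(3, 3, 3, 3), 2)), 1)
  set.seed(6)
  for (i in 1:40) {
    cells <- as.vector(stats::rmultinom(1, sample(4:30, 1), rep(1 / 4, 4)))
    tab <- matrix(cells, 2, 2)
    expect_equal(fisherExact2x2(tab),
                 fisherEnumOracle(cells[1], cells[3], cells[2], cells[4]),
                 tolerance = 1e-7)
  }
  expect_error(fisherExact2x2(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
})

test_that("odds ratios and confidence intervals behave per method", {
  woolf <- oddsRatioCI(matrix(c(10, 5, 2, 8), 2, byrow = TRUE),
                       method = "woolf_haldane")
  expect_equal(woolf$or, 8)                      # ad/bc = 80/10
  expect_false(woolf$corrected)
  expect_lt(woolf$ci_low, 8); expect_gt(woolf$ci_high, 8)

  null <- oddsRatioCI(matrix(c(4, 4, 4, 4), 2), method = "woolf_haldane")
  expect_equal(null$or, 1)
  expect_lte(null$ci_low, 1); expect_gte(null$ci_high, 1)

  zero <- oddsRatioCI(matrix(c(5, 0, 2, 7), 2, byrow = TRUE),
                      method = "woolf_haldane")
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or) && is.finite(zero$ci_high))

  exact <- oddsRatioCI(matrix(c(10, 5, 2, 8), 2, byrow = TRUE),
                       method = "conditional_exact")
  expect_true(exact$ci_low < exact$or && exact$or < exact$ci_high)

  expect_error(oddsRatioCI(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "entirely zero")
})

test_that("Wilcoxon rank-sum: exact enumeration on small untied samples", {
  # identical multisets are fully tied, so the tie-corrected approximation
  # is used and the null is exact: p = 1
  same <- wilcoxonRankSum(c(1, 2, 5), c(2, 5, 1))
  expect_equal(same$p, 1)

  res <- wilcoxonRankSum(c(1, 2), c(3, 4))
  expect_true(res$exact)
  expect_equal(res$p, 1 / 3)   # 2 * 1/6 over the C(4,2) rank assignments

  big <- wilcoxonRankSum(rnorm(40), rnorm(40) + 5)
  expect_false(big$exact)
  expect_lt(big$p, 0.001)
  expect_error(wilcoxonRankSum(numeric(0), 1:3), "nonempty")
})

test_that("Kruskal-Wallis reduces to the squared Wilcoxon z for two groups", {
  set.seed(12)
  x <- rnorm(15); y <- rnorm(12, 0.5)
  kw <- kruskalWallis(list(x, y))
  # z from the uncorrected normal approximation of the rank-sum statistic
  r <- rank(c(x, y))
  W <- sum(r[seq_along(x)])
  nx <- length(x); ny <- length(y)
  z <- (W - nx * (nx + ny + 1) / 2) / sqrt(nx * ny * (nx + ny + 1) / 12)
  expect_equal(kw$H, z^2, tolerance = 1e-10)
  expect_equal(kw$df, 1)

  flat <- kruskalWallis(list(c(2, 2), c(2, 2, 2)))
  expect_equal(flat$H, 0); expect_equal(flat$p, 1)
  expect_error(kruskalWallis(list(1:3)), "at least two")
})

test_that("Kruskal-Wallis p-values are uniform under a permutation null", {
  set.seed(91)
  vals <- rnorm(90)
  ps <- replicate(600, {
    idx <- sample(90)
    kruskalWallis(list(vals[idx[1:30]], vals[idx[31:60]], vals[idx[61:90]]))$p
  })
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Gaussian kernel density integrates to one and finds the age modes", {
  set.seed(2)
  ages <- c(rnorm(300, 55, 8), rnorm(300, 95, 8))
  den <- ageDensity(ages)
  expect_equal(den$bandwidth, bw.nrd0(ages))
  area <- sum(diff(den$x) * (head(den$density, -1) + tail(den$density, -1)) / 2)
  expect_equal(area, 1, tolerance = 1e-3)

  # two local maxima near the generating means
  peaks <- which(diff(sign(diff(den$density))) == -2) + 1
  modes <- den$x[peaks]
  expect_length(modes, 2)
  expect_lt(abs(modes[1] - 55), 6)
  expect_lt(abs(modes[2] - 95), 6)

  one <- ageDensity(rep(60, 5), bandwidth = 3)
  # density() evaluates on a binned grid; agreement to ~0.1% of the peak
  expect_lt(max(abs(one$density - dnorm(one$x, 60, 3))), 2e-4)
  expect_error(ageDensity(rep(60, 5)), "distinct")
  expect_error(ageDensity(1:5, bandwidth = 0), "> 0")
})

test_that("age-center comparison: identical samples give p = 1; methods agree when separated", {
  expect_equal(compareAgeCenters(c(50, 60, 70), c(70, 50, 60))$p, 1)
  set.seed(8)
  x <- rnorm(15, 55, 12); y <- rnorm(26, 95, 12)
  w <- compareAgeCenters(x, y, method = "wilcoxon")
  p <- compareAgeCenters(x, y, method = "permutation", nPermutations = 2000, seed = 4)
  expect_lt(w$p, 0.05); expect_lt(p$p, 0.05)
  # permutation test is reproducible under its seed
  p2 <- compareAgeCenters(x, y, method = "permutation", nPermutations = 2000, seed = 4)
  expect_identical(p, p2)
})

test_that("age separation at study-like sample sizes is detected in most cohorts", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- pmin(pmax(rnorm(15, 55, 12), 30), 180)
    y <- pmin(pmax(rnorm(26, 71, 12), 30), 180)
    if (compareAgeCenters(x, y)$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 80L)
})

test_that("Kaplan-Meier curves match hand-walked risk sets", {
  none <- kmEstimate(c(3, 8, 12), c(0, 0, 0))
  expect_true(all(none$survival == 1))

  two <- kmEstimate(c(2, 4), c(1, 1))
  expect_equal(kmSurvivalAt(two, c(0, 1.9, 2, 3.9, 4, 10)),
               c(1, 1, 0.5, 0.5, 0, 0))

  # event at 2 (n=3), censor at 3, event at 5: S(5) = (1 - 1/3)(1 - 1/1) = 0
  mixed <- kmEstimate(c(2, 3, 5), c(1, 0, 1))
  expect_equal(kmSurvivalAt(mixed, c(2, 3, 4.9, 5)), c(2/3, 2/3, 2/3, 0))

  # without censoring the curve is the empirical survival function
  set.seed(33)
  t <- round(rexp(40, 0.2), 2)
  km <- kmEstimate(t, rep(1, 40))
  for (q in c(1, 3, 7)) {
    expect_equal(kmSurvivalAt(km, q), mean(t > q), tolerance = 1e-12)
  }
  expect_true(all(diff(km$survival) <= 1e-12))
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("log-rank matches the hand oracle and is invariant to label swap", {
  time <- c(2, 4, 5, 7, 9, 12)
  event <- c(1, 1, 0, 1, 1, 0)
  group <- c("a", "b", "a", "b", "a", "b")
  res <- logrankTest(time, event, group)
  ora <- logrankOracle(time, event, group)
  expect_equal(res$chi2, ora$chi2, tolerance = 1e-10)
  expect_equal(res$p, ora$p, tolerance = 1e-10)

  swapped <- logrankTest(time, event, ifelse(group == "a", "b", "a"))
  expect_equal(swapped$chi2, res$chi2, tolerance = 1e-12)

  same <- logrankTest(rep(c(1, 3, 6), 2), rep(c(1, 1, 0), 2),
                      rep(c("a", "b"), each = 3))
  expect_equal(same$chi2, 0, tolerance = 1e-12)
  expect_equal(same$p, 1, tolerance = 1e-12)

  expect_warning(void <- logrankTest(c(1, 2, 3, 4), rep(0, 4),
                                     c("a", "a", "b", "b")), "no events")
  expect_equal(void$p, 1)
})

test_that("logistic regression recovers planted coefficients and flags separation", {
  set.seed(14)
  # null fit: slope ~ 0, intercept = logit of the event rate
  y0 <- rbinom(200, 1, 0.3)
  x0 <- rnorm(200)
  f0 <- logisticFit(y0, cbind(intercept = 1, x = x0))
  expect_true(f0$converged)
  expect_lt(abs(f0$coefficients["x"]), 3 * f0$se["x"])
  expect_equal(unname(f0$coefficients["intercept"]),
               log(mean(y0) / (1 - mean(y0))), tolerance = 0.35)

  # parameter recovery within 2 SE at n = 500
  beta <- c(-0.5, 0.8, -1.2)
  X <- cbind(intercept = 1, x1 = rnorm(500), x2 = rnorm(500))
  yr <- rbinom(500, 1, plogis(X %*% beta))
  fr <- logisticFit(yr, X)
  expect_true(fr$converged)
  expect_true(all(abs(fr$coefficients - beta) <= 2 * fr$se))

  # complete separation
  xs <- c(rnorm(20, -3), rnorm(20, 3))
  ys <- rep(c(0, 1), each = 20)
  fs <- logisticFit(ys, cbind(intercept = 1, x = xs))
  expect_true(fs$separated)
  expect_false(fs$converged)

  expect_error(logisticFit(y0, cbind(intercept = 1, a = x0, b = 2 * x0)),
               "aliased column\\(s\\): b")
})
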