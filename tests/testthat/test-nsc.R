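# independent loop oracle for the centroid statistics
nscOracle <- function(x, labels, mkVariant = "plus") {
  classes <- levels(factor(labels))
  n <- ncol(x); K <- length(classes)
  nk <- sapply(classes, function(cl) sum(labels == cl))
  xbar <- rowMeans(x)
  cent <- sapply(classes, function(cl) rowMeans(x[, labels == cl, drop = FALSE]))
  if (nrow(x) == 1) cent <- matrix(cent, 1, K, dimnames = list(rownames(x), classes))
  ss <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    for (cl in classes) for (j in which(labels == cl)) {
      ss[i] <- ss[i] + (x[i, j] - cent[i, cl])^2
    }
  }
  si <- sqrt(ss / (n - K))
  s0 <- median(si)
  mk <- if (mkVariant == "plus") sqrt(1 / nk + 1 / n) else sqrt(1 / nk - 1 / n)
  dik <- sapply(seq_along(classes), function(k)
    (cent[, k] - xbar) / (mk[k] * (si + s0)))
  if (nrow(x) == 1) dik <- matrix(dik, 1, K)
  list(xbar = xbar, cent = cent, si = si, s0 = s0, mk = mk, dik = dik)
}

test_that("fitNSC matches a brute-force oracle on the one-probe hand case", {
  x <- matrix(c(1, 3, 5, 7), 1, 4,
              dimnames = list("p1", c("a1", "a2", "b1", "b2")))
  lab <- c("A", "A", "B", "B")
  m <- fitNSC(x, lab)
  expect_equal(unname(m@overallCentroid), 4)
  expect_equal(unname(m@classCentroids[1, ]), c(2, 6))
  expect_equal(unname(m@pooledSD), sqrt(2))  # ss = 1+1+1+1 over n-K = 2
  expect_equal(m@s0, sqrt(2))
  ora <- nscOracle(x, lab)
  expect_equal(unname(m@dik), unname(ora$dik), tolerance = 1e-12)
  expect_equal(unname(m@mk), unname(ora$mk), tolerance = 1e-12)
})

test_that("fitNSC matches the loop oracle and the reconstruction identity on random instances", {
  set.seed(99)
  for (i in 1:15) {
    p <- sample(2:20, 1); nA <- sample(2:6, 1); nB <- sample(2:6, 1)
    x <- randomMatrix(p, nA + nB)
    lab <- rep(c("A", "B"), c(nA, nB))
    for (variant in c("plus", "minus")) {
      m <- fitNSC(x, lab, mkVariant = variant)
      ora <- nscOracle(x, lab, variant)
      expect_equal(unname(m@dik), unname(ora$dik), tolerance = 1e-12)
      expect_equal(m@s0, ora$s0, tolerance = 1e-12)
      # xbar_ik = xbar_i + mk (si + s0) dik, exactly
      recon <- m@overallCentroid + ((m@pooledSD + m@s0) %o% m@mk) * m@dik
      expect_equal(unname(recon), unname(m@classCentroids), tolerance = 1e-12)
      expect_equal(shrunkenCentroids(m), m@classCentroids, tolerance = 1e-12)
    }
  }
})

test_that("all-zero-variance training data is rejected", {
  x <- matrix(c(0, 0, 2, 2), 1, 4,
              dimnames = list("p1", c("a1", "a2", "b1", "b2")))
  expect_error(fitNSC(x, c("A", "A", "B", "B")), "zero pooled variance")
})

test_that("label swap flips the contrast pattern but not the predictions", {
  set.seed(5)
  x <- randomMatrix(12, 8)
  lab <- rep(c("A", "B"), each = 4)
  m1 <- fitNSC(x, lab)
  m2 <- fitNSC(x, ifelse(lab == "A", "B", "A"))
  # swapped membership: m2's class A is m1's class B (balanced classes)
  expect_equal(m2@dik[, "A"], m1@dik[, "B"], tolerance = 1e-12)
  expect_equal(m1@dik[, "A"], -m1@dik[, "B"], tolerance = 1e-12)
  # the induced partition is unchanged: labels swap with the label swap
  q <- randomMatrix(12, 5)
  p1 <- unname(predictNSC(m1, q)$class)
  p2 <- unname(predictNSC(m2, q)$class)
  expect_identical(ifelse(p1 == "A", "B", "A"), p2)
})

test_that("soft thresholding shrinks contrasts and centroids as specified", {
  set.seed(17)
  x <- randomMatrix(20, 10)
  m <- fitNSC(x, rep(c("A", "B"), each = 5))

  expect_equal(shrunkenContrasts(shrinkNSC(m, 0)), m@dik)

  dmax <- max(abs(m@dik))
  full <- shrinkNSC(m, dmax + 0.1)
  expect_equal(unname(shrunkenCentroids(full)),
               unname(cbind(m@overallCentroid, m@overallCentroid)))
  expect_length(survivingProbes(full), 0)

  # arithmetic of the soft threshold on a crafted contrast pair
  d <- c(1.5, -0.3)
  expect_equal(sign(d) * pmax(abs(d) - 0.5, 0), c(1.0, 0))
  expect_error(shrinkNSC(m, -1), ">= 0")

  # surviving-probe count is non-increasing in delta
  prev <- Inf
  for (delta in seq(0, dmax + 0.2, length.out = 12)) {
    nSurv <- length(survivingProbes(shrinkNSC(m, delta)))
    expect_lte(nSurv, prev)
    prev <- nSurv
  }
})

test_that("prediction probabilities normalize, ties warn, centroids self-classify", {
  set.seed(23)
  x <- randomMatrix(15, 9)
  m <- fitNSC(x, rep(c("A", "B"), c(4, 5)), priors = "uniform")
  q <- randomMatrix(15, 7)
  pred <- predictNSC(m, q)
  expect_equal(unname(rowSums(pred$probabilities)), rep(1, 7))

  # each shrunken class centroid is most probably its own class
  cent <- shrunkenCentroids(m)
  for (cl in m@classLabels) {
    p1 <- predictNSC(m, setNames(cent[, cl], m@probeIds))
    expect_identical(unname(p1$class), cl)
  }

  # full shrinkage + uniform priors forces a tie, broken by class order
  full <- shrinkNSC(m, max(abs(m@dik)) + 1)
  expect_warning(tied <- predictNSC(full, q), "tied")
  expect_true(all(tied$class == m@classLabels[1]))
  expect_equal(unname(tied$probabilities[, 1]), rep(0.5, 7))

  expect_error(predictNSC(m, q[1:10, ]), "lacks model probes")
})

test_that("the delta=0, s0=0, uniform-prior limit is the nearest standardized centroid rule", {
  set.seed(31)
  for (i in 1:100) {
    p <- sample(4:15, 1); nA <- sample(3:6, 1); nB <- sample(3:6, 1)
    x <- randomMatrix(p, nA + nB)
    lab <- rep(c("A", "B"), c(nA, nB))
    m <- fitNSC(x, lab, priors = "uniform", s0 = 0)
    q <- randomMatrix(p, 3)
    got <- predictNSC(m, q)$class

    # independent diagonal-covariance Gaussian classifier
    cent <- sapply(c("A", "B"), function(cl) rowMeans(x[, lab == cl, drop = FALSE]))
    si2 <- (rowSums((x[, lab == "A", drop = FALSE] - cent[, "A"])^2) +
            rowSums((x[, lab == "B", drop = FALSE] - cent[, "B"])^2)) /
           (ncol(x) - 2)
    want <- apply(q, 2, function(v) {
      dA <- sum((v - cent[, "A"])^2 / si2)
      dB <- sum((v - cent[, "B"])^2 / si2)
      if (dA <= dB) "A" else "B"
    })
    expect_identical(unname(got), unname(want))
  }
})

test_that("selectDelta is zero-error at delta 0 on separable data and reproducible", {
  set.seed(41)
  co <- simulateCohort(studyConfig(rng_seed = 77, n_probes = 300,
                                   n_signature_probes = 60, log2_effect = 3,
                                   noise_sd = 0.3))
  cd <- SummarizedExperiment::colData(co)
  x <- SummarizedExperiment::assay(co)[plantedProbes(co), cd$is_seed]
  lab <- cd$true_group[cd$is_seed]
  sel1 <- selectDelta(x, lab, delta_grid = c(0, 0.5, 1), folds = 7, seed = 9)
  expect_equal(sel1$cv_error$error[sel1$cv_error$delta == 0], 0)
  sel2 <- selectDelta(x, lab, delta_grid = c(0, 0.5, 1), folds = 7, seed = 9)
  expect_identical(sel1, sel2)
  # ties in error prefer the sparser (larger-delta) model
  expect_gte(sel1$delta, 0)
  expect_error(selectDelta(x, lab, delta_grid = c(0.5, 1)), "include 0")
})

test_that("vote bookkeeping: counts sum to repetitions and thresholds gate assignment", {
  co <- simulateCohort(studyConfig(rng_seed = 13, n_probes = 500,
                                   n_signature_probes = 80))
  cd <- SummarizedExperiment::colData(co)
  x <- perGeneMedianNormalize(co)[plantedProbes(co), ]
  seed <- cd$sample_id[cd$is_seed]
  lab <- factor(cd$true_group[cd$is_seed], levels = c("inflammation", "fibrosis"))
  vt <- repeatedCVClassify(x[, seed], lab, external = x[, setdiff(cd$sample_id, seed)],
                           seed = 3)
  vc <- voteCounts(vt)
  expect_setequal(vc$sample_id, cd$sample_id)
  expect_equal(vc$n_votes_inflammation + vc$n_votes_fibrosis + vc$n_abstain,
               rep(10L, nrow(vc)))
  expect_true(all(vc$n_abstain[vc$role == "train"] == 0L))
  # a unanimous sample is assigned; the separable cohort should have many
  unanimous <- vc$n_votes_inflammation == 10L | vc$n_votes_fibrosis == 10L
  expect_true(any(unanimous))
  expect_true(all(vc$assignment[unanimous] != "unclassified"))
})

test_that("a 5/5 vote split stays unclassified under the six-of-ten rule", {
  votes <- matrix(rep(c("inflammation", "fibrosis"), 5), 1, 10)
  rownames(votes) <- "s1"
  vt <- new("VoteTable", sampleIds = "s1", votes = votes,
            classLabels = c("inflammation", "fibrosis"), role = "external",
            voteThreshold = 6L)
  expect_identical(unname(assignments(vt)), "unclassified")
  # and 6/4 is assigned
  votes6 <- matrix(c(rep("inflammation", 6), rep("fibrosis", 4)), 1, 10,
                   dimnames = list("s2", NULL))
  vt6 <- new("VoteTable", sampleIds = "s2", votes = votes6,
             classLabels = c("inflammation", "fibrosis"), role = "external",
             voteThreshold = 6L)
  expect_identical(unname(assignments(vt6)), "inflammation")
})

test_that("assignments are invariant to probe order and to sample order", {
  co <- simulateCohort(studyConfig(rng_seed = 19, n_probes = 400,
                                   n_signature_probes = 80))
  cd <- SummarizedExperiment::colData(co)
  x <- perGeneMedianNormalize(co)[plantedProbes(co), ]
  seed <- cd$sample_id[cd$is_seed]
  ext <- setdiff(cd$sample_id, seed)
  lab <- setNames(factor(cd$true_group, levels = c("inflammation", "fibrosis")),
                  cd$sample_id)

  base <- assignments(repeatedCVClassify(x[, seed], lab[seed],
                                         external = x[, ext], seed = 8))

  # probe permutation: identical votes (alignment is by probe ID)
  perm <- sample(nrow(x))
  permuted <- assignments(repeatedCVClassify(x[perm, seed], lab[seed],
                                             external = x[perm, ext], seed = 8))
  expect_identical(permuted[names(base)], base)

  # sample permutation: same final assignments on separable data
  sp <- sample(seed); ep <- sample(ext)
  shuffled <- assignments(repeatedCVClassify(x[, sp], lab[sp],
                                             external = x[, ep], seed = 8))
  expect_identical(shuffled[names(base)], base)
})

test_that("fold and vote validation errors are informative", {
  x <- randomMatrix(10, 6)
  lab <- rep(c("A", "B"), each = 3)
  expect_error(repeatedCVClassify(x, lab, folds = 7), "exceeds")
  expect_error(repeatedCVClassify(x, lab, folds = 3, voteThreshold = 12),
               "1\\.\\.repetitions")
  expect_error(fitNSC(x, rep("A", 6)), "two classes")
  expect_error(fitNSC(x, c("A", rep("B", 5))), "at least two samples")
})
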