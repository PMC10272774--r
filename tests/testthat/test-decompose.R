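test_that("VAF matches the hand-computed worked case and its identities", {
  D <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] by row
  expect_equal(vaf(D, D), 1)
  colmean <- matrix(rep(colMeans(D), each = 2), 2, 2)
  expect_equal(vaf(D, colmean), 0)
  # columns of mean(D): (2, 3); ||D - mean(D)||^2 = 4; M errs by 1 in one cell
  M <- matrix(c(1, 3, 2, 5), 2, 2)
  expect_equal(vaf(D, M), 1 - 1 / 4)
  expect_error(vaf(D, matrix(0, 3, 2)), "shape")
  Dconst <- matrix(c(1, 1, 2, 2), 2, 2)  # no across-channel variance
  expect_error(vaf(Dconst, Dconst), "undefined")
})

test_that("SIMPLISMA purity follows the brute-force definition and shuns constant or duplicate columns", {
  set.seed(10)
  D <- matrix(runif(3 * 40), 3, 40)
  D[, 7] <- 0.5                      # constant column: sigma = 0
  ps <- simplismaSelect(D, 1, alpha = 0.03)
  expect_equal(ps@purity, oraclePurityFirst(D, 0.03), tolerance = 1e-12)
  expect_equal(ps@purity[7], 0)
  expect_identical(ps@selected, which.max(oraclePurityFirst(D, 0.03)))
  expect_equal(ps@initialC[, 1], D[, ps@selected], ignore_attr = TRUE)
  # a column proportional to the first selection gets weight zero
  # (scaled down so the original stays the purest and is picked first)
  D2 <- D
  D2[, 12] <- 0.5 * D[, ps@selected]
  ps2 <- simplismaSelect(D2, 2, alpha = 0.03)
  expect_equal(ps2@weights[12], 0, tolerance = 1e-10)
  expect_false(12 %in% ps2@selected)
  # rank-1 data cannot yield two distinguishable pure variables
  D1 <- outer(c(1, 2, 3), runif(30))
  expect_error(simplismaSelect(D1, 2), "degenerate")
  expect_error(simplismaSelect(D, 0), "r must")
  expect_error(simplismaSelect(D, 4), "r must")
})

test_that("on noiseless rest-phased data SIMPLISMA picks single-synergy samples seeding C near the truth", {
  gt <- smallTruth()
  D <- envValues(smallD())
  ps <- simplismaSelect(D, 2)
  S <- gt@STrue
  for (idx in ps@selected) {
    act <- S[, idx]
    # exactly one synergy is meaningfully active at a pure sample
    expect_lt(sort(act, decreasing = TRUE)[2], 0.05 * max(act))
  }
  mt <- matchSynergies(gt@CTrue, ps@initialC)
  expect_true(all(mt$cc >= 0.99))
})

test_that("MCR-ALS is an exact fixed point on factorable data and bit-reproducible", {
  gt <- smallTruth()
  D <- smallD()
  dec <- mcrAls(D, 2)
  expect_s4_class(dec, "SynergyDecomposition")
  expect_true(all(synergyWeights(dec) >= 0))
  expect_true(all(activations(dec) >= 0))
  resid <- sqrt(2 * tail(objectiveTrace(dec), 1))
  expect_lt(resid, 1e-8 * norm(envValues(D), "F"))
  expect_equal(decompositionVAF(dec), 1, tolerance = 1e-10)
  # scale/permutation recovery of the generating synergies
  mt <- matchSynergies(gt@CTrue, dec)
  expect_true(all(mt$cc >= 0.99))
  # no random state anywhere: repeated runs are identical
  dec2 <- mcrAls(D, 2)
  expect_identical(synergyWeights(dec), synergyWeights(dec2))
  expect_identical(activations(dec), activations(dec2))
})

test_that("MCR-ALS objective is non-increasing and matches the active-set ALS oracle", {
  skip_if_not_installed("pracma")
  set.seed(77)
  D <- envValues(smallD(noiseSigma = 0.1, seed = 3))[, 1:50]
  dec <- mcrAls(D, 2, stop = StoppingRule(qTol = 1e-8, maxIter = 500))
  tr <- objectiveTrace(dec)
  expect_true(all(diff(tr) <= 1e-9 * (1 + tr[-length(tr)])))
  ps <- simplismaSelect(D, 2)
  orc <- oracleALS(D, ps@initialC, iters = 500)
  expect_equal(tail(tr, 1), orc$objective, tolerance = 1e-6)
  # the projection variant still yields a valid non-negative factorization
  decP <- mcrAls(D, 2, nnls = "project")
  expect_true(all(synergyWeights(decP) >= 0))
  expect_true(all(activations(decP) >= 0))
  expect_error(mcrAls(-D, 2), "non-negative")
})

test_that("NMF objective decreases monotonically for every seed and honors the stopping rule", {
  D <- envValues(smallD(noiseSigma = 0.05, seed = 2))
  for (seed in 1:10) {
    dec <- nmfSynergy(D, 2, seed = seed)
    tr <- objectiveTrace(dec)
    expect_true(all(diff(tr) <= 1e-9 * (1 + tr[-length(tr)])))
    expect_lte(dec@nIter, 1000L)
    expect_true(all(synergyWeights(dec) >= 0))
    expect_true(all(activations(dec) >= 0))
    # stop reason is either |Q| <= qTol or the iteration cap
    if (dec@nIter < 1000L && dec@nIter > 1L) {
      n <- length(tr)
      Q <- 100 * (tr[n] - tr[n - 1]) / tr[n - 1]
      expect_lte(abs(Q), 0.01)
    }
  }
})

test_that("NMF usually reaches the exact factorization on exactly factorable data", {
  D <- envValues(smallD())
  vafs <- vapply(1:10, function(s)
    decompositionVAF(nmfSynergy(D, 2, seed = s)), 1)
  # random restarts can hit local optima; most seeds must get there
  expect_gte(sum(vafs >= 0.999), 8)
})

test_that("PCA reproduces the data with a complete basis and matches an SVD oracle", {
  set.seed(4)
  D <- envValues(smallD(noiseSigma = 0.08, seed = 6))[, 1:200]
  full <- pcaSynergy(D, nrow(D))
  expect_equal(reconstruct(full), D, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(decompositionVAF(full), 1, tolerance = 1e-10)
  ev <- full@details$eigenvalues
  expect_true(all(diff(ev) <= 1e-12))
  # SVD of the centered data is an independent route to the components
  Dc <- D - rowMeans(D)
  sv <- svd(Dc)
  dec <- pcaSynergy(D, 2)
  for (k in 1:2) {
    a <- activations(dec)[k, ]
    b <- sv$d[k] * sv$v[, k]
    expect_equal(abs(cor(a, b)), 1, tolerance = 1e-8)
    expect_equal(min(sum((a - b)^2), sum((a + b)^2)), 0,
                 tolerance = 1e-8 * sum(a^2))
  }
  # sign convention: dominant entry of each eigenvector is positive
  C <- synergyWeights(dec)
  for (k in 1:2) expect_gt(C[which.max(abs(C[, k])), k], 0)
  # VAF is non-decreasing in the component count
  vafs <- vapply(1:3, function(k) decompositionVAF(pcaSynergy(D, k)), 1)
  expect_true(all(diff(vafs) >= -1e-12))
})

test_that("recorded VAF is internally consistent for all three methods", {
  D <- envValues(smallD(noiseSigma = 0.05, seed = 8))
  for (dec in list(mcrAls(D, 2), nmfSynergy(D, 2, seed = 3),
                   pcaSynergy(D, 2)))
    expect_equal(decompositionVAF(dec), vaf(D, reconstruct(dec)),
                 tolerance = 1e-12)
})

test_that("order selection returns the smallest synergy count exceeding the VAF threshold", {
  # noiseless rank-1 data
  S1 <- makeActivationProfiles(4, 50, 1, seed = 3)
  D1 <- outer(c(0.4, 1, 0.7), 1) %*% S1
  expect_equal(selectOrder(D1, "mcr_als"), 1L, ignore_attr = TRUE)
  # the 2-synergy study fixture with 5% noise
  fx <- defaultFixture()
  sel <- selectOrder(fx$session$emg, "mcr_als", vafThreshold = 0.8, rMax = 3)
  expect_equal(sel, 2L, ignore_attr = TRUE)
  vafs <- attr(sel, "vaf")
  expect_lte(vafs[1], 0.8)
  expect_gt(vafs[2], 0.8)
  # impossible threshold falls back to rMax with a warning
  expect_warning(
    selRM <- selectOrder(envValues(fx$session$emg), "pca",
                         vafThreshold = 1 - 1e-15, rMax = 2),
    "returning rMax")
  expect_equal(selRM, 2L, ignore_attr = TRUE)
})

test_that("synergy matching is invariant to column permutation and positive rescaling", {
  set.seed(12)
  C <- matrix(runif(9), 3, 3)
  perm <- c(3, 1, 2)
  C2 <- C[, perm] %*% diag(c(2, 0.5, 7))
  mt <- matchSynergies(C, C2)
  expect_equal(order(perm), mt$order[order(seq_along(perm))],
               ignore_attr = TRUE)
  expect_equal(mt$cc, rep(1, 3), tolerance = 1e-12)
})
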