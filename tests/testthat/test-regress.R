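test_that("analytic BPTT gradients agree with central finite differences", {
  ns <- asNamespace("synergykit")
  set.seed(1)
  p <- ns$.bilstmInit(2L, 3L, 2L, 42L)
  Tn <- 7L
  N <- 3L
  X <- array(rnorm(2 * N * Tn), c(2, N, Tn))
  Y <- matrix(rnorm(N * Tn), N, Tn)
  lg <- ns$.bilstmLossGrad(p, X, Y)
  fd <- function(mutate) {
    eps <- 1e-6
    (ns$.bilstmLossGrad(mutate(p, eps), X, Y)$loss -
       ns$.bilstmLossGrad(mutate(p, -eps), X, Y)$loss) / (2 * eps)
  }
  relErr <- c()
  for (li in c(1, 2, 4)) for (nm in c("W", "U", "b")) {
    for (k in sample(length(p$weights[[li]][[nm]]), 3)) {
      gAn <- lg$grad$weights[[li]][[nm]][k]
      gNu <- fd(function(pp, e) {
        pp$weights[[li]][[nm]][k] <- pp$weights[[li]][[nm]][k] + e
        pp
      })
      relErr <- c(relErr, abs(gAn - gNu) / max(1e-8, abs(gAn) + abs(gNu)))
    }
  }
  gNu <- fd(function(pp, e) { pp$Wy[1] <- pp$Wy[1] + e; pp })
  relErr <- c(relErr, abs(lg$grad$Wy[1] - gNu) /
                max(1e-8, abs(lg$grad$Wy[1]) + abs(gNu)))
  expect_lt(max(relErr), 1e-4)
})

test_that("the default architecture audit: five bidirectional layers of 48 units with dropout 0.3", {
  S <- makeActivationProfiles(3, 60, 2, seed = 2)
  ang <- AngleTrace(rep(seq(0, 89, length.out = 60), 3), 50)
  model <- trainAngleRegressor(S, ang, windowLength = 40, stride = 40,
                               epochs = 1, seed = 1)
  cfg <- model@config
  expect_equal(cfg$nLayers, 5L)
  expect_equal(cfg$hiddenUnits, 48L)
  expect_equal(cfg$dropout, 0.3)
  w <- regressorWeights(model)$weights
  expect_length(w, 10)  # 5 layers x 2 directions
  H <- 48
  expect_equal(dim(w[[1]]$W), c(4 * H, 2))       # first layer reads r = 2
  expect_equal(dim(w[[3]]$W), c(4 * H, 2 * H))   # deeper layers read 2H
  expect_equal(dim(w[[1]]$U), c(4 * H, H))
  nPar <- sum(vapply(w, function(d)
    length(d$W) + length(d$U) + length(d$b), 1)) +
    length(regressorWeights(model)$Wy) + 1
  audit <- 2 * (4 * H * (2 + H) + 4 * H) +               # layer 1
    4 * 2 * (4 * H * (2 * H + H) + 4 * H) +              # layers 2-5
    2 * H + 1                                            # read-out
  expect_equal(nPar, audit)
})

test_that("training standardizes features, is seed-reproducible, and predicts deterministically", {
  set.seed(6)
  n <- 300
  S <- rbind(abs(sin(seq_len(n) / 10)), abs(cos(seq_len(n) / 15)))
  ang <- AngleTrace(45 + 40 * sin(seq_len(n) / 20), 50)
  fit <- function() trainAngleRegressor(S, ang, nLayers = 1, hiddenUnits = 6,
                                        windowLength = 50, stride = 25,
                                        epochs = 3, seed = 7)
  m1 <- fit()
  m2 <- fit()
  expect_identical(regressorWeights(m1), regressorWeights(m2))
  expect_identical(m1@trainingLog, m2@trainingLog)
  z <- (S - m1@featureStats$center) / m1@featureStats$scale
  expect_equal(rowMeans(z), c(0, 0), tolerance = 1e-9)
  expect_equal(apply(z, 1, sd), c(1, 1), tolerance = 1e-6)
  p1 <- predictAngle(m1, S)
  p2 <- predictAngle(m1, S)
  expect_identical(angleValues(p1), angleValues(p2))
  expect_length(angleValues(p1), n)
  expect_error(predictAngle(m1, rbind(S, S)), "dimension mismatch")
  expect_error(trainAngleRegressor(S, AngleTrace(rep(1, 10), 50)),
               "aligned")
  expect_error(trainAngleRegressor(S[, 1:20], AngleTrace(rep(1, 20), 50),
                                   windowLength = 50), "shorter")
})

test_that("a constant angle target is learned to within a degree", {
  set.seed(3)
  n <- 240
  S <- rbind(runif(n), runif(n))
  ang <- AngleTrace(rep(37, n), 50)
  m <- trainAngleRegressor(S, ang, nLayers = 1, hiddenUnits = 4,
                           windowLength = 40, stride = 20, epochs = 5,
                           dropout = 0, seed = 2)
  p <- angleValues(predictAngle(m, S))
  expect_lt(max(abs(p - 37)), 1)
})

test_that("a learnable smooth activation-to-angle mapping reaches held-out CC >= 0.95", {
  # construct angle as a known smooth function of two burst activations,
  # train on the first 70% and score the held-out 30%
  prof <- makeActivationProfiles(12, 100, 2, seed = 9)
  n <- ncol(prof)
  angle <- 80 * (cumsum(prof[1, ] - prof[2, ]) -
                   min(cumsum(prof[1, ] - prof[2, ])))
  angle <- angle / max(angle) * 85
  cut <- floor(0.7 * n)
  m <- trainAngleRegressor(prof[, 1:cut], AngleTrace(angle[1:cut], 50),
                           nLayers = 2, hiddenUnits = 16, dropout = 0.1,
                           windowLength = 100, stride = 10, epochs = 40,
                           seed = 4)
  heldOut <- predictAngle(m, prof[, (cut + 1):n])
  expect_gte(pearsonCC(angleValues(heldOut), angle[(cut + 1):n]), 0.95)
  # training-set fit is at least as demanding
  fitted <- predictAngle(m, prof[, 1:cut])
  expect_gte(pearsonCC(angleValues(fitted), angle[1:cut]), 0.95)
})
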