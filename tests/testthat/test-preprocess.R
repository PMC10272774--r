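test_that("envelope of a pure sinusoid settles at the rectified mean", {
  fs <- 2000
  tt <- seq(0, 4, by = 1 / fs)
  amp <- 1.7
  x <- amp * sin(2 * pi * 50 * tt)
  env <- makeEnvelope(rbind(x, x), fs, band = c(20, 450), envCutoff = 4)
  v <- envValues(env)
  mid <- v[1, seq(round(0.3 * ncol(v)), round(0.7 * ncol(v)))]
  # full-wave rectified sine has mean 2/pi * amplitude
  expect_equal(mean(mid), 2 / pi * amp, tolerance = 0.02)
  expect_lt(sd(mid) / mean(mid), 0.05)
  expect_equal(ncol(v), length(tt))
})

test_that("envelope operator is non-negative, kills zero input and is positively homogeneous", {
  fs <- 1000
  z <- matrix(0, 2, 500)
  expect_equal(max(abs(envValues(makeEnvelope(z, fs, band = c(20, 450))))), 0)
  set.seed(3)
  x <- matrix(rnorm(2 * 800), 2, 800)
  e1 <- envValues(makeEnvelope(x, fs, band = c(20, 450)))
  expect_true(all(e1 >= 0))
  e3 <- envValues(makeEnvelope(3 * x, fs, band = c(20, 450)))
  expect_equal(e3, 3 * e1, tolerance = 1e-8)
})

test_that("envelope input validation catches bad bands and non-finite data", {
  x <- matrix(rnorm(300), 2, 150)
  expect_error(makeEnvelope(x, 100, band = c(20, 450)), "Nyquist")
  expect_error(makeEnvelope(x, 1000, band = c(450, 20)), "low < high")
  x[1, 5] <- NA
  expect_error(makeEnvelope(x, 1000), "non-finite")
})

test_that("trial concatenation preserves order and validates inputs", {
  a <- EnvelopeMatrix(matrix(runif(300), 3, 100), 50)
  b <- EnvelopeMatrix(matrix(runif(300), 3, 100), 50)
  one <- concatTrials(list(a))
  expect_equal(envValues(one), envValues(a))
  ab <- concatTrials(list(a, b))
  expect_equal(dim(ab), c(3, 200))
  expect_equal(envValues(ab)[, 100 + 37], envValues(b)[, 37])
  bad <- EnvelopeMatrix(matrix(runif(200), 2, 100), 50)
  expect_error(concatTrials(list(a, bad)), "channel")
  bad2 <- EnvelopeMatrix(matrix(runif(300), 3, 100), 100)
  expect_error(concatTrials(list(a, bad2)), "sampling")
})

test_that("max normalization scales peaks to one, spares zero channels, and is idempotent", {
  v <- rbind(5 * runif(80), numeric(80), 0.2 * runif(80))
  env <- EnvelopeMatrix(v, 50)
  nrm <- normalizeChannels(env, "max")
  expect_equal(unname(apply(envValues(nrm), 1, max)), c(1, 0, 1))
  expect_equal(envValues(nrm)[2, ], numeric(80), ignore_attr = TRUE)
  # shape preserved: perfect correlation channel-wise
  expect_equal(cor(envValues(nrm)[1, ], v[1, ]), 1)
  again <- normalizeChannels(nrm, "max")
  expect_equal(envValues(again), envValues(nrm))
  expect_identical(envValues(normalizeChannels(env, "none")), envValues(env))
})

test_that("EnvelopeMatrix enforces non-negativity and more samples than channels", {
  expect_error(EnvelopeMatrix(matrix(-1, 2, 10), 50), "non-negative")
  expect_error(EnvelopeMatrix(matrix(1, 5, 4), 50), "n > m")
  expect_error(EnvelopeMatrix(matrix(NaN, 2, 10), 50), "finite")
})
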