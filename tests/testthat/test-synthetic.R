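test_that("activation profiles are smooth non-negative bursts with rest phases", {
  S <- makeActivationProfiles(nCycles = 30, samplesPerCycle = 200, r = 2,
                              seed = 1)
  expect_equal(dim(S), c(2, 6000))
  expect_true(all(S >= 0))
  # every synergy rests in every cycle: per-cycle minimum <= 1% of its max
  for (k in 1:2) for (cy in 1:30) {
    seg <- S[k, (cy - 1) * 200 + 1:200]
    expect_lte(min(seg), 0.01 * max(seg))
  }
  # rows are not near-collinear
  expect_lt(abs(cor(S[1, ], S[2, ])), 0.9)
  # single-synergy case is a burst train with rest
  S1 <- makeActivationProfiles(5, 100, 1, seed = 2)
  expect_true(all(S1 >= 0))
  for (cy in 1:5) {
    seg <- S1[1, (cy - 1) * 100 + 1:100]
    expect_lte(min(seg), 0.01 * max(seg))
  }
  expect_error(makeActivationProfiles(0, 200, 2), "required")
  expect_error(makeActivationProfiles(5, 10, 2), "required")
  expect_error(makeActivationProfiles(5, 200, 0), "required")
})

test_that("generation is reproducible and seeds are independent of caller RNG", {
  a <- makeActivationProfiles(3, 50, 2, seed = 11)
  set.seed(999)  # caller state must not leak in
  b <- makeActivationProfiles(3, 50, 2, seed = 11)
  expect_identical(a, b)
  gt1 <- makeGroundTruth(nCycles = 3, samplesPerCycle = 40, seed = 4)
  gt2 <- makeGroundTruth(nCycles = 3, samplesPerCycle = 40, seed = 4)
  expect_identical(gt1@CTrue, gt2@CTrue)
  s1 <- synthesizeSession(gt1, 2, seed = 8)
  s2 <- synthesizeSession(gt2, 2, seed = 8)
  expect_identical(envValues(s1$emg), envValues(s2$emg))
  expect_identical(s1$accel@ax, s2$accel@ax)
})

test_that("noiseless unit-gain sessions reproduce C S exactly and invert to the true angle", {
  gt <- smallTruth()
  ses <- synthesizeSession(gt, 1, seed = 3)
  expect_identical(gt@dayGains[1, ], rep(1, 3))
  expect_equal(envValues(ses$emg), gt@CTrue %*% gt@STrue,
               tolerance = 0, ignore_attr = TRUE)
  # accelerometer inversion without filtering is exact
  ang <- angleFromAccel(ses$accel, cutoff = NULL, gRef = 1)
  expect_lt(angleError(ang, ses$angle), 1e-10)
  # with the default low-pass it still reproduces the truth to < 0.01 deg
  gt30 <- makeGroundTruth(noiseSigma = 0, seed = 7)
  s30 <- synthesizeSession(gt30, 1, seed = 2)
  ang30 <- angleFromAccel(s30$accel, gRef = 1)
  expect_lt(angleError(ang30, s30$angle), 0.01)
  # angle endpoints: theta = 90 gives Ax = g
  thr <- gt@angleTrue * pi / 180
  expect_equal(ses$accel@ax, sin(thr), tolerance = 1e-12)
})

test_that("noisy sessions respect the accelerometer bound and stay decomposable", {
  gt <- makeGroundTruth(noiseSigma = 0.05, seed = 7)
  ses <- synthesizeSession(gt, 1, seed = 8)
  expect_true(all(envValues(ses$emg) >= 0))
  expect_true(all(abs(ses$accel@ax) <= 1 * (1 + 3 * 0.05) + 1e-12))
  # the rank-2 truth reconstruction still explains the noisy data well
  expect_gt(vaf(ses$emg, gt@CTrue %*% gt@STrue), 0.8)
  expect_error(synthesizeSession(gt, 9, seed = 1), "unknown day")
})

test_that("protocol layout matches the multi-day design", {
  ss <- makeProtocol(nSubjects = 12, nDays = 5, seed = 2, nCycles = 2,
                     samplesPerCycle = 30, restSeconds = 0.2)
  # day 1 has two sets, days 2..5 one set: 12 x (2 + 4) = 72 recordings
  expect_length(ss@recordings, 72)
  expect_equal(sort(unique(vapply(ss@recordings, `[[`, 1L, "day"))), 1:5)
  # 7/12 split into amplitude groups
  expect_equal(unname(table(ss@groups)[c("high", "low")]), c(7L, 5L),
               ignore_attr = TRUE)
  # high group scaled up relative to low
  highAmp <- mean(vapply(which(ss@groups == "high"),
                         function(s) mean(ss@truths[[s]]@CTrue), 1))
  lowAmp <- mean(vapply(which(ss@groups == "low"),
                        function(s) mean(ss@truths[[s]]@CTrue), 1))
  expect_gt(highAmp, lowAmp)
  ss1 <- makeProtocol(nSubjects = 1, nDays = 1, seed = 2, nCycles = 2,
                      samplesPerCycle = 30, restSeconds = 0.2)
  expect_length(ss1@recordings, 2)
  expect_error(makeProtocol(nSubjects = 0), ">= 1")
})

test_that("session CSVs round-trip through write and read", {
  ss <- makeProtocol(nSubjects = 1, nDays = 1, seed = 6, nCycles = 2,
                     samplesPerCycle = 30, restSeconds = 0.2)
  dir <- withr::local_tempdir()
  paths <- writeSessionSet(ss, dir)
  expect_length(paths, 2)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- readSessionCSV(paths[1])
  rec <- ss@recordings[[1]]
  expect_equal(envValues(back$emg), envValues(rec$emg), tolerance = 1e-12)
  expect_equal(back$accel@ax, rec$accel@ax, tolerance = 1e-12)
  expect_equal(samplingRate(back$emg), samplingRate(rec$emg))
  expect_equal(angleValues(back$angle), angleValues(rec$angle),
               tolerance = 1e-12)
})
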