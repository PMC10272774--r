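# Independent oracles and small fixtures shared across tests.

# Alternating non-negative least squares using pracma's Lawson-Hanson
# active-set solver, column by column -- an implementation-independent
# reference for the MCR-ALS objective.
oracleALS <- function(D, C0, iters = 500) {
  C <- C0
  S <- matrix(0, ncol(C0), ncol(D))
  for (it in seq_len(iters)) {
    for (j in seq_len(ncol(D)))
      S[, j] <- pracma::lsqnonneg(C, D[, j])$x
    for (i in seq_len(nrow(D)))
      C[i, ] <- pracma::lsqnonneg(t(S), D[i, ])$x
  }
  list(C = C, S = S, objective = 0.5 * sum((D - C %*% S)^2))
}

# Brute-force first-round SIMPLISMA purity over all columns.
oraclePurityFirst <- function(D, alpha) {
  mu <- colMeans(D)
  sig <- sqrt(colMeans(D^2) - mu^2)
  sig / (mu + alpha * max(mu))
}

# Small noiseless rank-2 fixture with obvious rest phases.
smallTruth <- function(noiseSigma = 0, seed = 5) {
  makeGroundTruth(nCycles = 4L, samplesPerCycle = 50L, nDays = 2L,
                  noiseSigma = noiseSigma, seed = seed)
}

smallD <- function(noiseSigma = 0, seed = 5, day = 1, sessionSeed = 9) {
  synthesizeSession(smallTruth(noiseSigma, seed), day, seed = sessionSeed)$emg
}

# The 3-channel, 2-synergy, 30-cycle, 5%-noise study fixture.
defaultFixture <- function(seed = 7) {
  gt <- makeGroundTruth(seed = seed)
  list(truth = gt, session = synthesizeSession(gt, 1, seed = seed + 1))
}
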