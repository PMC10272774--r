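## Muscle-synergy extraction: MCR-ALS (SIMPLISMA initialisation + exact
## non-negative alternating least squares), multiplicative-update NMF and a
## PCA baseline, plus VAF-based selection of the synergy count.

.asD <- function(D) {
  if (is(D, "EnvelopeMatrix")) envValues(D) else as.matrix(D)
}

# Exact non-negative least squares min_{X >= 0} ||A X - B||_F, column-wise,
# by enumeration of support sets: the optimal column solution equals the
# unconstrained solution on its own passive set, which is feasible, so it
# always appears among the candidates; we keep the feasible candidate with
# the smallest residual. Vectorised over all columns of B; exponential in
# ncol(A), intended for the small synergy counts (r <= ~10) of EMG work.
# Singular support subsets are skipped, which also covers rank-deficient
# factors.
.nnlsSolve <- function(A, B) {
  r <- ncol(A)
  n <- ncol(B)
  X <- matrix(0, r, n)
  best <- colSums(B * B)                 # empty-support residual
  supports <- lapply(seq_len(2^r - 1L), function(code)
    which(bitwAnd(code, bitwShiftL(1L, seq_len(r) - 1L)) > 0L))
  supports <- supports[order(lengths(supports))]
  for (sup in supports) {
    As <- A[, sup, drop = FALSE]
    G <- crossprod(As)
    sol <- tryCatch(solve(G, crossprod(As, B)), error = function(e) NULL)
    if (is.null(sol)) next
    ftol <- -1e-9 * (1 + apply(abs(sol), 2L, max))
    feas <- colSums(sol < rep(ftol, each = nrow(sol))) == 0L
    if (!any(feas)) next
    res <- colSums((B - As %*% sol)^2)
    upd <- feas & (res < best)
    if (any(upd)) {
      X[, upd] <- 0
      X[sup, upd] <- pmax(sol[, upd, drop = FALSE], 0)
      best[upd] <- res[upd]
    }
  }
  X
}

.objective <- function(D, C, S) 0.5 * sum((D - C %*% S)^2)

#' Variance accounted for by a reconstruction
#'
#' VAF = 1 - ||D - M||_F^2 / ||D - mean(D)||_F^2, where mean(D) replaces
#' every column of D by its across-channel mean (each time sample's mean over
#' muscles). VAF is 1 for a perfect reconstruction, 0 when M carries no more
#' information than the per-sample channel mean, and can be negative for
#' worse reconstructions.
#'
#' @param D an [EnvelopeMatrix-class] or matrix.
#' @param M reconstruction matrix of the same shape.
#' @return the VAF fraction (<= 1).
#' @examples
#' D <- matrix(c(1, 3, 2, 4), 2, 2)
#' vaf(D, D)  # 1
#' @export
vaf <- function(D, M) {
  D <- .asD(D)
  M <- .asD(M)
  if (!all(dim(D) == dim(M))) stop("D and M must have the same shape")
  cm <- colMeans(D)
  den <- sum(sweep(D, 2L, cm)^2)
  if (den == 0) stop("VAF undefined: D has no across-channel variance")
  1 - sum((D - M)^2) / den
}

#' SIMPLISMA pure-variable selection
#'
#' Selects `r` pure variables among the time samples (columns) of the
#' envelope matrix. A pure variable is a sample during which, ideally, a
#' single synergy is active, so its channel-intensity vector seeds the
#' corresponding column of the synergy matrix C.
#'
#' The purity of candidate column i is p_i = w_i * sigma_i / (mu_i + a),
#' with mu_i and sigma_i the across-channel mean and (population) standard
#' deviation of the column, and a = alpha * max(mu) a noise offset that
#' stops low-intensity noise columns from looking pure. The first selection
#' uses w = 1; later selections weight each candidate by the determinant of
#' the correlation-around-the-origin matrix of the candidate joined with the
#' already-selected columns (each column scaled by
#' sqrt(mu^2 + (sigma + a)^2)), which drives the weight of any column
#' proportional to an already-selected one to zero. Exact purity ties go to
#' the lowest index.
#'
#' @param D an [EnvelopeMatrix-class] or non-negative matrix.
#' @param r number of pure variables to select (<= min(channels, samples)).
#' @param alpha noise-offset fraction, conventionally 1-5% (default 0.03).
#' @return a [PurityState-class]; slot `initialC` holds the selected columns
#'   as the initial synergy matrix.
#' @export
simplismaSelect <- function(D, r, alpha = 0.03) {
  D <- .asD(D)
  if (any(D < 0)) stop("D must be non-negative")
  m <- nrow(D)
  n <- ncol(D)
  if (r < 1 || r > min(m, n)) stop("r must lie in 1..min(m, n)")
  if (alpha <= 0) stop("alpha must be positive")
  mu <- colMeans(D)
  sig <- sqrt(pmax(colMeans(D^2) - mu^2, 0))
  off <- alpha * max(mu)
  if (off == 0) stop("degenerate input: all columns are zero")
  base <- sig / (mu + off)
  lambda <- sqrt(mu^2 + (sig + off)^2)
  Y <- sweep(D, 2L, ifelse(lambda > 0, lambda, 1), "/")
  cDiag <- colSums(Y^2) / m
  selected <- integer(0)
  w <- rep(1, n)
  p <- base
  pScale <- max(base)
  for (k in seq_len(r)) {
    if (k > 1L) {
      Ysel <- Y[, selected, drop = FALSE]
      A <- crossprod(Ysel) / m
      b <- crossprod(Ysel, Y) / m          # k-1 x n
      detA <- det(A)
      q <- colSums(b * solve(A, b))
      w <- pmax(detA * (cDiag - q), 0)
      p <- w * base
    }
    p[selected] <- 0
    if (max(p) <= 1e-12 * max(pScale, 1e-300))
      stop("degenerate input: fewer than r distinguishable columns ",
           "(selection stalled at ", k - 1L, " pure variables)")
    selected <- c(selected, which.max(p))
  }
  new("PurityState", purity = p, alpha = alpha, weights = w,
      selected = selected, initialC = D[, selected, drop = FALSE])
}

#' MCR-ALS synergy extraction
#'
#' Multivariate curve resolution by alternating least squares with
#' non-negativity on both factors, initialised deterministically from the
#' SIMPLISMA pure variables (so repeated runs on the same data are
#' bit-identical). Each iteration solves the two least-squares subproblems
#'   S = argmin ||D - C S||_F  and  C = argmin ||D - C S||_F
#' under non-negativity; with the default exact solver each half-step is the
#' true constrained minimiser, so the objective trace
#' f = 0.5 ||D - C S||_F^2 is non-increasing. Iteration stops when the
#' relative objective change in percent, Q = 100 (f_{l+1} - f_l) / f_l,
#' satisfies |Q| <= `stop@qTol`, or at `stop@maxIter` iterations.
#'
#' @param D an [EnvelopeMatrix-class] or non-negative matrix (channels x
#'   samples).
#' @param r synergy count.
#' @param stop a [StoppingRule-class] (default |Q| <= 0.01% or 1000
#'   iterations).
#' @param alpha SIMPLISMA noise-offset fraction.
#' @param nnls "exact" (default) solves each non-negative least-squares
#'   subproblem exactly; "project" solves the unconstrained normal equations
#'   and clips negatives to zero (faster, follows the textbook update
#'   literally, but the objective trace is no longer guaranteed monotone).
#' @return a [SynergyDecomposition-class] with method "mcr_als".
#' @examples
#' gt <- makeGroundTruth(nCycles = 4, samplesPerCycle = 50, noiseSigma = 0)
#' D <- synthesizeSession(gt, 1, seed = 1)$emg
#' dec <- mcrAls(D, r = 2)
#' decompositionVAF(dec)
#' @export
mcrAls <- function(D, r, stop = StoppingRule(), alpha = 0.03,
                   nnls = c("exact", "project")) {
  nnls <- match.arg(nnls)
  D <- .asD(D)
  if (any(!is.finite(D))) stop("D must be finite")
  if (any(D < 0)) stop("D must be non-negative")
  if (r < 1) stop("r must be >= 1")
  ps <- simplismaSelect(D, r, alpha)
  C <- ps@initialC
  S <- matrix(0, r, ncol(D))
  trace <- numeric(0)
  fPrev <- Inf
  fallback <- FALSE
  updateS <- function(C) {
    if (nnls == "exact") return(.nnlsSolve(C, D))
    sol <- tryCatch(solve(crossprod(C), crossprod(C, D)),
                    error = function(e) NULL)
    if (is.null(sol)) { fallback <<- TRUE; return(.nnlsSolve(C, D)) }
    pmax(sol, 0)
  }
  updateC <- function(S) {
    if (nnls == "exact") return(t(.nnlsSolve(t(S), t(D))))
    sol <- tryCatch(t(solve(tcrossprod(S), S %*% t(D))),
                    error = function(e) NULL)
    if (is.null(sol)) { fallback <<- TRUE; return(t(.nnlsSolve(t(S), t(D)))) }
    pmax(sol, 0)
  }
  nIter <- 0L
  for (l in seq_len(stop@maxIter)) {
    S <- updateS(C)
    C <- updateC(S)
    f <- .objective(D, C, S)
    trace <- c(trace, f)
    nIter <- l
    # exact factorizations sit at f ~ 0 where the relative change Q is all
    # round-off; treat machine-precision residuals as converged
    if (f <= .Machine$double.eps^2 * sum(D * D)) break
    if (is.finite(fPrev)) {
      if (fPrev == 0) break
      Q <- 100 * (f - fPrev) / fPrev
      if (abs(Q) <= stop@qTol) break
    }
    fPrev <- f
  }
  SynergyDecomposition(C, S, "mcr_als", nIter = nIter,
                       objectiveTrace = trace, vaf = vaf(D, C %*% S),
                       details = list(selected = ps@selected, alpha = alpha,
                                      nnls = nnls, fallback = fallback,
                                      converged = nIter < stop@maxIter))
}

#' NMF synergy extraction (multiplicative updates)
#'
#' Non-negative matrix factorization of the envelope matrix by Lee-Seung
#' multiplicative updates minimising f = 0.5 ||D - C S||_F^2, started from a
#' seeded uniform(0, 1] random initialisation. The random start makes the
#' factor order and scale seed-dependent — the non-uniqueness that motivates
#' the deterministic MCR-ALS alternative. Stopping follows the same |Q|
#' rule as [mcrAls()].
#'
#' @inheritParams mcrAls
#' @param seed integer seed for the random initial factors.
#' @param eps epsilon floor added to update denominators so zero rows or
#'   columns in D cannot cause division by zero.
#' @return a [SynergyDecomposition-class] with method "nmf".
#' @export
nmfSynergy <- function(D, r, stop = StoppingRule(), seed = 1L, eps = 1e-12) {
  D <- .asD(D)
  if (any(!is.finite(D))) stop("D must be finite")
  if (any(D < 0)) stop("D must be non-negative")
  if (r < 1) stop("r must be >= 1")
  m <- nrow(D)
  n <- ncol(D)
  init <- .withSeed(seed, list(C = matrix(1 - runif(m * r), m, r),
                               S = matrix(1 - runif(r * n), r, n)))
  C <- init$C * sqrt(mean(D) + eps)
  S <- init$S
  trace <- numeric(0)
  fPrev <- Inf
  nIter <- 0L
  for (l in seq_len(stop@maxIter)) {
    S <- S * crossprod(C, D) / (crossprod(C) %*% S + eps)
    C <- C * tcrossprod(D, S) / (C %*% tcrossprod(S) + eps)
    f <- .objective(D, C, S)
    trace <- c(trace, f)
    nIter <- l
    if (is.finite(fPrev)) {
      if (fPrev == 0) break
      Q <- 100 * (f - fPrev) / fPrev
      if (abs(Q) <= stop@qTol) break
    }
    fPrev <- f
  }
  SynergyDecomposition(C, S, "nmf", nIter = nIter, objectiveTrace = trace,
                       vaf = vaf(D, C %*% S),
                       details = list(seed = seed,
                                      converged = nIter < stop@maxIter))
}

#' PCA synergy baseline
#'
#' Eigendecomposition of the m x m covariance of the channel signals over
#' time. The top-k eigenvectors (descending eigenvalue) form C; the component
#' time courses are S = C' (D - Dbar) with Dbar the per-channel time means.
#' No non-negativity constraint applies, so C and S may carry negative
#' entries; each eigenvector's sign is fixed so its largest-magnitude entry
#' is positive. The recorded VAF uses the reconstruction C S + Dbar.
#'
#' @param D an [EnvelopeMatrix-class] or matrix (channels x samples).
#' @param k number of components (<= channels).
#' @return a [SynergyDecomposition-class] with method "pca"; `details` holds
#'   the eigenvalues, the channel means, and a flag for (near-)repeated
#'   eigenvalues, whose eigenvectors are only determined up to rotation.
#' @export
pcaSynergy <- function(D, k) {
  D <- .asD(D)
  m <- nrow(D)
  if (k < 1 || k > m) stop("k must lie in 1..channels")
  mu <- rowMeans(D)
  Dc <- D - mu
  V <- tcrossprod(Dc) / (ncol(D) - 1)
  e <- eigen(V, symmetric = TRUE)
  C <- e$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(C[, j]))
    if (C[i, j] < 0) C[, j] <- -C[, j]
  }
  S <- crossprod(C, Dc)
  M <- C %*% S + mu
  gaps <- abs(diff(e$values))
  repeated <- any(gaps <= 1e-10 * max(abs(e$values), 1e-300))
  SynergyDecomposition(C, S, "pca", nIter = 0L, vaf = vaf(D, M),
                       details = list(eigenvalues = e$values,
                                      channelMeans = mu,
                                      repeatedEigenvalues = repeated))
}

#' Reconstruction from a decomposition
#'
#' C S for the non-negative methods; C S plus the stored channel means for
#' PCA (whose factors describe the centered data).
#'
#' @param decomp a [SynergyDecomposition-class].
#' @return the reconstruction matrix, same shape as the original D.
#' @export
reconstruct <- function(decomp) {
  M <- decomp@C %*% decomp@S
  if (decomp@method == "pca") M <- M + decomp@details$channelMeans
  M
}

#' Select the synergy count by the VAF criterion
#'
#' Returns the smallest r in 1..rMax whose decomposition reconstructs D with
#' VAF above `vafThreshold` (default 0.80). If no r qualifies, returns
#' `rMax` with a warning.
#'
#' @param D an [EnvelopeMatrix-class] or non-negative matrix.
#' @param method "mcr_als", "nmf" or "pca".
#' @param vafThreshold VAF that must be exceeded (default 0.80).
#' @param rMax largest candidate synergy count (default: channel count).
#' @param stop a [StoppingRule-class] for the iterative methods.
#' @param alpha SIMPLISMA offset (mcr_als only).
#' @param seed seed for the NMF initialisation.
#' @return the selected synergy count (integer); the per-r VAF values are
#'   attached as attribute `"vaf"`.
#' @export
selectOrder <- function(D, method = c("mcr_als", "nmf", "pca"),
                        vafThreshold = 0.8, rMax = NULL,
                        stop = StoppingRule(), alpha = 0.03, seed = 1L) {
  method <- match.arg(method)
  D <- .asD(D)
  m <- nrow(D)
  if (is.null(rMax)) rMax <- m
  if (rMax > m) stop("rMax must be <= channel count")
  vafs <- numeric(0)
  for (r in seq_len(rMax)) {
    dec <- switch(method,
      mcr_als = mcrAls(D, r, stop = stop, alpha = alpha),
      nmf = nmfSynergy(D, r, stop = stop, seed = seed),
      pca = pcaSynergy(D, r))
    vafs[r] <- decompositionVAF(dec)
    if (vafs[r] > vafThreshold)
      return(structure(as.integer(r), vaf = vafs))
  }
  warning("no synergy count reached VAF > ", vafThreshold,
          "; returning rMax = ", rMax)
  structure(as.integer(rMax), vaf = vafs)
}

#' Match synergy columns between two decompositions
#'
#' Greedy maximum-correlation assignment between the columns of a reference
#' synergy matrix and those of a second one (columns unit-normalised first;
#' the factorization's scale is not identifiable). Used to compare runs,
#' days and methods, since factor order is arbitrary.
#'
#' @param ref,other channels x r matrices (or
#'   [SynergyDecomposition-class] objects).
#' @return list with `order` (for each reference column, the matched column
#'   of `other`) and `cc` (the Pearson correlation of each matched pair).
#' @export
matchSynergies <- function(ref, other) {
  A <- if (is(ref, "SynergyDecomposition")) ref@C else as.matrix(ref)
  B <- if (is(other, "SynergyDecomposition")) other@C else as.matrix(other)
  if (!all(dim(A) == dim(B))) stop("synergy matrices must share dimensions")
  normc <- function(M) sweep(M, 2L, pmax(sqrt(colSums(M^2)), 1e-300), "/")
  An <- normc(A)
  Bn <- normc(B)
  # identical (scaled) columns correlate at exactly 1 by definition;
  # bypassing cor() there keeps repeated deterministic runs at CC = 1
  # without round-off
  ccm <- matrix(0, ncol(A), ncol(B))
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B)))
    ccm[i, j] <- if (identical(An[, i], Bn[, j])) 1
                 else suppressWarnings(cor(An[, i], Bn[, j]))
  ccm[!is.finite(ccm)] <- -2
  r <- ncol(A)
  ord <- integer(r)
  cc <- numeric(r)
  work <- ccm
  for (step in seq_len(r)) {
    ij <- which(work == max(work), arr.ind = TRUE)[1L, ]
    ord[ij[1L]] <- ij[2L]
    cc[ij[1L]] <- ccm[ij[1L], ij[2L]]
    work[ij[1L], ] <- -Inf
    work[, ij[2L]] <- -Inf
  }
  list(order = ord, cc = cc)
}
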