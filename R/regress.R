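## Bi-LSTM regression from synergy activation coefficients to joint angle.
##
## The recurrent stack itself lives in compiled code (src/bilstm.cpp); this
## file handles feature construction (synergy matching + standardization),
## windowing, training and sequence-to-sequence prediction.

.standardize <- function(S, stats = NULL) {
  if (is.null(stats)) {
    center <- rowMeans(S)
    scale <- apply(S, 1L, sd)
    scale[scale == 0] <- 1
    stats <- list(center = center, scale = scale)
  }
  list(values = (S - stats$center) / stats$scale, stats = stats)
}

# (features x n) series -> array (features, nWindows, T) of sliding windows
.windowArray <- function(F, starts, wl) {
  A <- array(0, c(nrow(F), length(starts), wl))
  for (t in seq_len(wl)) A[, , t] <- F[, starts + t - 1L, drop = FALSE]
  A
}

#' Build activation-coefficient features for the angle regressor
#'
#' Returns the activation matrix S of a decomposition as the feature
#' sequence. When a trained [AngleRegressor-class] is supplied, the rows are
#' first reordered by matching this decomposition's synergy columns against
#' the model's training-day reference (factor order is arbitrary across runs
#' and days), then standardized with the training-set statistics.
#'
#' @param decomp a [SynergyDecomposition-class] (or a plain feature matrix).
#' @param model optional trained [AngleRegressor-class].
#' @return an r x n numeric feature matrix.
#' @export
buildFeatures <- function(decomp, model = NULL) {
  S <- if (is(decomp, "SynergyDecomposition")) activations(decomp)
       else as.matrix(decomp)
  if (is.null(model)) return(S)
  if (nrow(S) != model@featureDim)
    stop("feature dimension mismatch: model expects ", model@featureDim,
         " rows")
  if (is(decomp, "SynergyDecomposition") && length(model@referenceC) &&
      !anyNA(model@referenceC)) {
    mt <- matchSynergies(model@referenceC, synergyWeights(decomp))
    S <- S[mt$order, , drop = FALSE]
  }
  .standardize(S, model@featureStats)$values
}

#' Train the bidirectional LSTM angle regressor
#'
#' Maps standardized synergy activation coefficients to joint angle,
#' sequence-to-sequence (one angle per timestep). The default architecture
#' is five bidirectional LSTM layers with 48 hidden units per direction and
#' dropout 0.3 after each recurrent layer; training minimises mean squared
#' error on the standardized angle over sliding windows with Adam.
#'
#' @param decomp a [SynergyDecomposition-class] (or feature matrix) of the
#'   training session.
#' @param angle an [AngleTrace-class] (or numeric vector, degrees) aligned
#'   sample-for-sample with the features.
#' @param nLayers number of bidirectional LSTM layers.
#' @param hiddenUnits hidden units per direction and layer.
#' @param dropout dropout fraction after each recurrent layer.
#' @param windowLength training window length in samples.
#' @param stride window stride in samples.
#' @param epochs training epochs.
#' @param learningRate Adam step size.
#' @param batchSize windows per gradient step.
#' @param seed integer seed (weights, shuffling, dropout); fixed seed gives
#'   a reproducible model.
#' @return an [AngleRegressor-class].
#' @export
trainAngleRegressor <- function(decomp, angle, nLayers = 5L,
                                hiddenUnits = 48L, dropout = 0.3,
                                windowLength = 100L, stride = 20L,
                                epochs = 30L, learningRate = 1e-3,
                                batchSize = 32L, seed = 1L) {
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  if (windowLength < 1) stop("windowLength must be >= 1")
  sr <- if (is(angle, "AngleTrace")) samplingRate(angle) else NA_real_
  a <- if (is(angle, "AngleTrace")) angleValues(angle) else as.numeric(angle)
  S <- if (is(decomp, "SynergyDecomposition")) activations(decomp)
       else as.matrix(decomp)
  n <- ncol(S)
  if (length(a) != n) stop("features and angles must be aligned")
  if (n < windowLength) stop("series shorter than windowLength")
  fs <- .standardize(S)
  as_ <- .standardize(matrix(a, 1L))
  starts <- seq(1L, n - windowLength + 1L, by = stride)
  X <- .windowArray(fs$values, starts, windowLength)
  Y <- matrix(0, length(starts), windowLength)
  for (t in seq_len(windowLength)) Y[, t] <- as_$values[1L, starts + t - 1L]
  params <- .bilstmInit(nrow(S), as.integer(hiddenUnits),
                        as.integer(nLayers), as.integer(seed))
  fit <- .bilstmTrain(params, X, Y, as.integer(epochs), learningRate,
                      dropout, as.integer(batchSize), as.integer(seed))
  trainingLog <- fit$log
  fit$log <- NULL
  refC <- if (is(decomp, "SynergyDecomposition")) synergyWeights(decomp)
          else matrix(NA_real_, 0, 0)
  new("AngleRegressor", params = fit,
      config = list(nLayers = as.integer(nLayers),
                    hiddenUnits = as.integer(hiddenUnits), dropout = dropout,
                    windowLength = as.integer(windowLength),
                    stride = as.integer(stride), epochs = as.integer(epochs),
                    learningRate = learningRate,
                    batchSize = as.integer(batchSize),
                    seed = as.integer(seed), samplingRate = sr),
      featureDim = as.integer(nrow(S)), trainingLog = trainingLog,
      featureStats = fs$stats, angleStats = as_$stats, referenceC = refC)
}

#' Predict a joint-angle sequence
#'
#' Builds matched, standardized features from the decomposition (see
#' [buildFeatures()]), runs the network over windows covering the whole
#' series (overlaps averaged), and returns one angle per input sample on the
#' original degree scale. Dropout is inactive at inference, so repeated
#' calls are identical.
#'
#' @param model a trained [AngleRegressor-class].
#' @param decomp a [SynergyDecomposition-class] or feature matrix of the
#'   session to predict.
#' @param samplingRate sampling rate of the returned [AngleTrace-class];
#'   defaults to the training sampling rate.
#' @return an [AngleTrace-class] of the same length as the input.
#' @export
predictAngle <- function(model, decomp, samplingRate = NULL) {
  F <- buildFeatures(decomp, model)
  n <- ncol(F)
  wl <- min(model@config$windowLength, n)
  starts <- unique(c(seq(1L, n - wl + 1L, by = wl), n - wl + 1L))
  X <- .windowArray(F, starts, wl)
  P <- .bilstmPredict(model@params, X)
  acc <- numeric(n)
  cnt <- numeric(n)
  for (w in seq_along(starts)) {
    idx <- starts[w] + seq_len(wl) - 1L
    acc[idx] <- acc[idx] + P[w, ]
    cnt[idx] <- cnt[idx] + 1
  }
  z <- acc / cnt
  theta <- z * model@angleStats$scale[1L] + model@angleStats$center[1L]
  sr <- if (!is.null(samplingRate)) samplingRate
        else if (!is.na(model@config$samplingRate)) model@config$samplingRate
        else 1
  AngleTrace(pmin(pmax(theta, -90), 90), sr)
}

#' Weight matrices of a trained regressor
#'
#' Exposes the network parameters (per layer and direction: input weights W,
#' recurrent weights U, bias b; plus the linear read-out) for inspection,
#' e.g. parameter-count audits.
#'
#' @param model an [AngleRegressor-class].
#' @return the parameter list.
#' @export
regressorWeights <- function(model) model@params
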