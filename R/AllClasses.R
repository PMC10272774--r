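#' @import methods
#' @importFrom stats sd cor rnorm runif setNames
NULL

#' EnvelopeMatrix: non-negative sEMG envelope data
#'
#' Container for a preprocessed surface-EMG envelope matrix, the
#' channels-by-samples matrix D that synergy models factorise as D = C S + E.
#' Rows are muscle channels, columns are time samples.
#'
#' @slot values numeric matrix, channels x samples, element-wise >= 0.
#' @slot samplingRate sampling rate of the envelope in Hz.
#' @slot channelNames character vector of channel (muscle) labels.
#'
#' @examples
#' env <- EnvelopeMatrix(matrix(abs(rnorm(300)), 3, 100), samplingRate = 50)
#' dim(env)
#' @export EnvelopeMatrix
#' @exportClass EnvelopeMatrix
setClass("EnvelopeMatrix",
  representation(
    values = "matrix",
    samplingRate = "numeric",
    channelNames = "character"
  )
)

setValidity("EnvelopeMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("'values' must be a numeric matrix")
  if (any(!is.finite(v))) return("envelope values must be finite")
  if (any(v < 0)) return("envelope values must be non-negative")
  if (nrow(v) >= ncol(v))
    return("envelope must have more time samples than channels (n > m)")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("'samplingRate' must be a single positive number")
  if (length(object@channelNames) != nrow(v))
    return("'channelNames' length must equal the channel count")
  TRUE
})

#' @param values channels x samples numeric matrix of non-negative envelopes.
#' @param samplingRate sampling rate in Hz.
#' @param channelNames optional channel labels; defaults to ch1..chm.
#' @rdname EnvelopeMatrix-class
EnvelopeMatrix <- function(values, samplingRate, channelNames = NULL) {
  values <- as.matrix(values)
  if (is.null(channelNames)) {
    channelNames <- rownames(values)
    if (is.null(channelNames)) channelNames <- paste0("ch", seq_len(nrow(values)))
  }
  rownames(values) <- channelNames
  new("EnvelopeMatrix", values = values, samplingRate = as.numeric(samplingRate),
      channelNames = channelNames)
}

#' SynergyDecomposition: result of a synergy extraction
#'
#' Holds the synergy matrix C (channels x r), the activation coefficient
#' matrix S (r x samples), the extraction method, the per-iteration objective
#' trace f = 0.5 * ||D - CS||_F^2 and the final VAF of the reconstruction.
#' For PCA the "reconstruction" adds the channel means back, and C/S are not
#' sign-constrained.
#'
#' @slot C numeric matrix, channels x r synergy weights.
#' @slot S numeric matrix, r x samples activation coefficients.
#' @slot method one of "mcr_als", "nmf", "pca".
#' @slot r synergy count.
#' @slot nIter iterations actually used (0 for pca).
#' @slot objectiveTrace per-iteration objective values.
#' @slot vaf variance accounted for by the reconstruction.
#' @slot details list of method-specific records (eigenvalues, channel means,
#'   convergence flags, selected pure variables, ...).
#' @export SynergyDecomposition
#' @exportClass SynergyDecomposition
setClass("SynergyDecomposition",
  representation(
    C = "matrix", S = "matrix", method = "character", r = "integer",
    nIter = "integer", objectiveTrace = "numeric", vaf = "numeric",
    details = "list"
  )
)

setValidity("SynergyDecomposition", function(object) {
  if (!object@method %in% c("mcr_als", "nmf", "pca"))
    return("method must be one of 'mcr_als', 'nmf', 'pca'")
  if (ncol(object@C) != object@r || nrow(object@S) != object@r)
    return("C must be m x r and S must be r x n")
  if (object@method %in% c("mcr_als", "nmf") &&
      (any(object@C < 0) || any(object@S < 0)))
    return("C and S must be non-negative for mcr_als and nmf")
  TRUE
})

SynergyDecomposition <- function(C, S, method, nIter = 0L,
                                 objectiveTrace = numeric(0), vaf = NA_real_,
                                 details = list()) {
  # Class must be named explicitly: an argument named C would otherwise
  # partially match new()'s Class formal
  new(Class = "SynergyDecomposition", C = C, S = S, method = method,
      r = as.integer(ncol(C)), nIter = as.integer(nIter),
      objectiveTrace = as.numeric(objectiveTrace), vaf = as.numeric(vaf),
      details = details)
}

#' PurityState: record of a SIMPLISMA pure-variable selection
#'
#' @slot purity purity value of each candidate time sample at the last
#'   selection round.
#' @slot alpha noise-offset fraction used in the purity denominator.
#' @slot weights determinant-based weights at the last selection round.
#' @slot selected ordered indices of the selected pure variables (columns).
#' @slot initialC channels x r matrix of the selected columns' intensities.
#' @exportClass PurityState
setClass("PurityState",
  representation(
    purity = "numeric", alpha = "numeric", weights = "numeric",
    selected = "integer", initialC = "matrix"
  )
)

setValidity("PurityState", function(object) {
  if (anyDuplicated(object@selected)) return("selected indices must be distinct")
  if (length(object@alpha) != 1L || object@alpha <= 0)
    return("alpha must be a single positive fraction")
  TRUE
})

#' StoppingRule: iteration control for NMF and MCR-ALS
#'
#' Iterations stop when the absolute relative change of the objective between
#' successive iterations, expressed in percent (Q), falls to `qTol` or when
#' `maxIter` iterations have run.
#'
#' @slot qTol convergence tolerance on |Q| in percent (default 0.01).
#' @slot maxIter maximum number of iterations (default 1000).
#' @param qTol,maxIter see slots.
#' @examples
#' StoppingRule()
#' @export StoppingRule
#' @exportClass StoppingRule
setClass("StoppingRule", representation(qTol = "numeric", maxIter = "integer"))

setValidity("StoppingRule", function(object) {
  if (object@qTol <= 0) return("qTol must be > 0")
  if (object@maxIter < 1L) return("maxIter must be >= 1")
  TRUE
})

#' @rdname StoppingRule-class
StoppingRule <- function(qTol = 0.01, maxIter = 1000L) {
  new("StoppingRule", qTol = as.numeric(qTol), maxIter = as.integer(maxIter))
}

#' AccelTrace: tri-axial accelerometer samples
#'
#' @slot ax,ay,az per-sample accelerations along the sensor axes; units are
#'   arbitrary (g or m/s^2) because gravity calibration makes the angle
#'   formula unit-free.
#' @slot samplingRate sampling rate in Hz.
#' @slot gRef gravity magnitude in the same units (NA before calibration).
#' @export AccelTrace
#' @exportClass AccelTrace
setClass("AccelTrace",
  representation(ax = "numeric", ay = "numeric", az = "numeric",
                 samplingRate = "numeric", gRef = "numeric")
)

setValidity("AccelTrace", function(object) {
  n <- length(object@ax)
  if (length(object@ay) != n || length(object@az) != n)
    return("ax, ay, az must have equal length")
  if (any(!is.finite(c(object@ax, object@ay, object@az))))
    return("accelerometer samples must be finite")
  if (!is.na(object@gRef) && object@gRef <= 0) return("gRef must be positive")
  TRUE
})

#' @param ax,ay,az numeric vectors of per-sample accelerations.
#' @param samplingRate sampling rate in Hz.
#' @param gRef gravity reference magnitude (NA until calibrated).
#' @rdname AccelTrace-class
AccelTrace <- function(ax, ay, az, samplingRate, gRef = NA_real_) {
  new("AccelTrace", ax = as.numeric(ax), ay = as.numeric(ay),
      az = as.numeric(az), samplingRate = as.numeric(samplingRate),
      gRef = as.numeric(gRef))
}

#' AngleTrace: joint-angle time series in degrees
#'
#' @slot theta per-sample joint angle in degrees.
#' @slot samplingRate sampling rate in Hz.
#' @export AngleTrace
#' @exportClass AngleTrace
setClass("AngleTrace",
  representation(theta = "numeric", samplingRate = "numeric"))

setValidity("AngleTrace", function(object) {
  if (any(!is.finite(object@theta))) return("theta must be finite")
  if (any(object@theta < -90 - 1e-9) || any(object@theta > 90 + 1e-9))
    return("theta must lie in [-90, 90] degrees")
  TRUE
})

#' @param theta numeric vector of angles in degrees within [-90, 90].
#' @param samplingRate sampling rate in Hz.
#' @rdname AngleTrace-class
AngleTrace <- function(theta, samplingRate) {
  new("AngleTrace", theta = as.numeric(theta),
      samplingRate = as.numeric(samplingRate))
}

#' GroundTruth: generating model of a synthetic subject
#'
#' The generating side of D = C S + E for one synthetic subject: true synergy
#' weights, activation time courses, the angle trajectory that produced them,
#' per-day channel gains and the additive-noise level.
#'
#' @slot CTrue channels x r non-negative synergy matrix.
#' @slot STrue r x samples non-negative activation time courses.
#' @slot angleTrue samples-long elbow angle series in degrees, within [0, 90].
#' @slot dayGains days x channels matrix of strictly positive gains.
#' @slot dayShifts list (per day) of channels x r additive perturbations of
#'   CTrue (clipped so the perturbed C stays non-negative).
#' @slot noiseSigma additive noise sd as a fraction of the signal RMS.
#' @slot samplingRate envelope sampling rate in Hz.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(CTrue = "matrix", STrue = "matrix", angleTrue = "numeric",
                 dayGains = "matrix", dayShifts = "list",
                 noiseSigma = "numeric", samplingRate = "numeric"))

setValidity("GroundTruth", function(object) {
  if (any(object@CTrue < 0) || any(object@STrue < 0))
    return("CTrue and STrue must be non-negative")
  if (any(object@angleTrue < 0) || any(object@angleTrue > 90))
    return("angleTrue must lie in [0, 90] degrees")
  if (any(object@dayGains <= 0)) return("day gains must be strictly positive")
  if (ncol(object@dayGains) != nrow(object@CTrue))
    return("dayGains must have one column per channel")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' SessionSet: grouped synthetic recordings by subject and day
#'
#' @slot recordings list of recordings; each is a list with elements
#'   subject, day, set, emg (EnvelopeMatrix), accel (AccelTrace),
#'   angle (AngleTrace), group.
#' @slot truths list of per-subject GroundTruth objects.
#' @slot samplingRate common sampling rate in Hz.
#' @slot groups named character vector mapping subject id to group label.
#' @exportClass SessionSet
setClass("SessionSet",
  representation(recordings = "list", truths = "list",
                 samplingRate = "numeric", groups = "character"))

setValidity("SessionSet", function(object) {
  if (length(object@recordings) == 0L) return(TRUE)
  m <- nrow(object@recordings[[1]]$emg@values)
  for (rec in object@recordings) {
    if (nrow(rec$emg@values) != m)
      return("all recordings must share the channel count")
    if (rec$emg@samplingRate != object@samplingRate)
      return("all recordings must share the sampling rate")
  }
  TRUE
})

#' AngleRegressor: trained bidirectional LSTM angle model
#'
#' Sequence-to-sequence regressor mapping standardized synergy activation
#' features to joint angle. Parameters live in a flat list of numeric
#' matrices (input, recurrent and bias weights per layer and direction plus
#' the linear read-out), so the model round-trips exactly through R
#' serialisation.
#'
#' @slot params list of weight matrices of the bidirectional LSTM stack.
#' @slot config list of architecture and training settings.
#' @slot featureDim number of feature rows expected at prediction time.
#' @slot trainingLog per-epoch mean squared error on the standardized angle.
#' @slot featureStats list with per-row center/scale of the training features.
#' @slot angleStats list with center/scale of the training angle.
#' @slot referenceC channels x r synergy matrix of the training-day
#'   decomposition, used to order features of later sessions consistently.
#' @exportClass AngleRegressor
setClass("AngleRegressor",
  representation(params = "list", config = "list", featureDim = "integer",
                 trainingLog = "numeric", featureStats = "list",
                 angleStats = "list", referenceC = "matrix"))

setValidity("AngleRegressor", function(object) {
  if (object@featureDim < 1L) return("featureDim must be >= 1")
  TRUE
})
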