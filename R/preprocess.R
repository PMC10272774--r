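## Raw sEMG -> non-negative envelope matrix.
##
## Standard synergy-pipeline chain: DC removal, zero-phase Butterworth
## band-pass, full-wave rectification, zero-phase Butterworth low-pass, clip
## at zero. All cutoffs configurable; synthetic envelope-level data can skip
## this stage entirely (the generator already emits envelopes).

# Zero-phase filtering with odd reflection padding at both ends to suppress
# edge transients (signal::filtfilt alone does not pad).
.filtfiltPad <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1L, 3L * (max(length(filt$b), length(filt$a)) - 1L) * 4L)
  if (pad < 1L) return(signal::filtfilt(filt, x))
  pre <- 2 * x[1] - x[seq(pad + 1L, 2L)]
  post <- 2 * x[n] - x[seq(n - 1L, n - pad)]
  y <- signal::filtfilt(filt, c(pre, x, post))
  y[seq(pad + 1L, pad + n)]
}

#' Compute the non-negative sEMG envelope
#'
#' Converts raw multi-channel sEMG into the envelope matrix that synergy
#' models factorise: per channel, the DC offset is removed, the signal is
#' band-pass filtered (4th-order Butterworth, zero-phase), full-wave
#' rectified, low-pass filtered (4th-order Butterworth, zero-phase) and
#' clipped at zero.
#'
#' @param raw channels x samples numeric matrix of raw sEMG.
#' @param samplingRate sampling rate in Hz; must exceed twice the band's
#'   upper edge.
#' @param band numeric length-2, band-pass corner frequencies in Hz.
#' @param envCutoff envelope low-pass cutoff in Hz.
#' @param order Butterworth order for both filters.
#' @return an [EnvelopeMatrix-class] with the same number of samples.
#' @examples
#' fs <- 2000
#' x <- matrix(sin(2 * pi * 50 * seq(0, 1, by = 1 / fs)), nrow = 1)
#' env <- makeEnvelope(rbind(x, x), fs)
#' @export
makeEnvelope <- function(raw, samplingRate, band = c(20, 450), envCutoff = 4,
                         order = 4) {
  raw <- as.matrix(raw)
  if (any(!is.finite(raw))) stop("raw sEMG contains non-finite values")
  nyq <- samplingRate / 2
  if (length(band) != 2L || band[1] <= 0 || band[2] <= band[1])
    stop("band must be (low, high) with 0 < low < high")
  if (band[2] >= nyq) stop("band upper edge must be below Nyquist")
  if (envCutoff <= 0 || envCutoff >= nyq)
    stop("envCutoff must lie in (0, Nyquist)")
  bp <- signal::butter(order, band / nyq, type = "pass")
  lp <- signal::butter(order, envCutoff / nyq, type = "low")
  env <- t(apply(raw, 1L, function(x) {
    x <- x - mean(x)
    x <- .filtfiltPad(bp, x)
    pmax(.filtfiltPad(lp, abs(x)), 0)
  }))
  EnvelopeMatrix(env, samplingRate, rownames(raw))
}

#' Concatenate trials along time
#'
#' Joins several envelope matrices sample-wise; all inputs must share the
#' channel count and sampling rate. Channel order is preserved.
#'
#' @param envelopes list of [EnvelopeMatrix-class] objects.
#' @return one [EnvelopeMatrix-class] with the summed sample count.
#' @export
concatTrials <- function(envelopes) {
  stopifnot(length(envelopes) >= 1L)
  m <- nrow(envValues(envelopes[[1]]))
  sr <- samplingRate(envelopes[[1]])
  for (e in envelopes) {
    if (nrow(envValues(e)) != m) stop("mismatched channel counts")
    if (samplingRate(e) != sr) stop("mismatched sampling rates")
  }
  EnvelopeMatrix(do.call(cbind, lapply(envelopes, envValues)), sr,
                 channelNames(envelopes[[1]]))
}

#' Normalize envelope channels
#'
#' With `mode = "max"` each channel is divided by its maximum so the channel
#' peaks at 1; identically-zero channels are left untouched. `mode = "none"`
#' returns the input unchanged. Positive per-channel scaling leaves channel
#' shapes (and hence correlation-based comparisons) invariant.
#'
#' @param env an [EnvelopeMatrix-class].
#' @param mode "max" or "none".
#' @return an [EnvelopeMatrix-class].
#' @export
normalizeChannels <- function(env, mode = c("max", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(env)
  v <- envValues(env)
  mx <- apply(v, 1L, max)
  scl <- ifelse(mx > 0, mx, 1)
  EnvelopeMatrix(v / scl, samplingRate(env), channelNames(env))
}
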