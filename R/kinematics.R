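## Elbow angle from a tri-axial accelerometer under the quasi-static
## assumption: during slow flexion/extension the sensed x-axis acceleration
## is the gravity component alone, so theta = 90 - arccos(Ax / g).

#' Calibrate the gravity reference from a static segment
#'
#' Estimates the gravity magnitude as the mean of sqrt(Ax^2 + Ay^2 + Az^2)
#' over a resting segment. The segment must be long enough and actually
#' static: its magnitude variation (coefficient of variation) must stay
#' below `maxCV`.
#'
#' @param static an [AccelTrace-class] covering at least `minSeconds` of rest.
#' @param minSeconds minimum rest duration (default 0.5 s).
#' @param maxCV maximum allowed sd/mean of the magnitude (default 0.2).
#' @return the gravity magnitude `gRef` in the trace's units.
#' @examples
#' tr <- AccelTrace(rep(0.6, 100), rep(0, 100), rep(0.8, 100), 100)
#' calibrateGravity(tr)  # 1
#' @export
calibrateGravity <- function(static, minSeconds = 0.5, maxCV = 0.2) {
  stopifnot(is(static, "AccelTrace"))
  n <- length(static@ax)
  if (n < minSeconds * static@samplingRate)
    stop("static segment must cover at least ", minSeconds, " s")
  mag <- sqrt(static@ax^2 + static@ay^2 + static@az^2)
  g <- mean(mag)
  if (g <= 0 || sd(mag) / g > maxCV)
    stop("segment is not static: magnitude variation too large")
  g
}

#' Joint angle from the accelerometer x-axis
#'
#' Applies theta = 90 - arccos(Ax / gRef) degrees after zero-phase low-pass
#' filtering of Ax. The arccos argument is clamped to [-1, 1] so sensor noise
#' at the trajectory endpoints cannot produce NaN. Ax = 0 maps to 0 degrees
#' (horizontal forearm at rest), Ax = gRef to the 90-degree task endpoint.
#'
#' @param trace an [AccelTrace-class] with `gRef` set (see
#'   [calibrateGravity()]), or pass `gRef` explicitly.
#' @param cutoff low-pass cutoff in Hz (default 2); `NULL` skips filtering.
#' @param gRef optional gravity reference overriding the trace's slot.
#' @return an [AngleTrace-class] of the same length.
#' @examples
#' tr <- AccelTrace(c(0, 0.5, 1), c(0, 0, 0), c(1, 0.87, 0), 100, gRef = 1)
#' angleValues(angleFromAccel(tr, cutoff = NULL))  # 0, 30, 90
#' @export
angleFromAccel <- function(trace, cutoff = 2, gRef = NULL) {
  stopifnot(is(trace, "AccelTrace"))
  g <- if (!is.null(gRef)) gRef else trace@gRef
  if (is.na(g) || g <= 0)
    stop("gravity reference missing: calibrate first or pass gRef")
  ax <- trace@ax
  if (!is.null(cutoff)) {
    nyq <- trace@samplingRate / 2
    if (cutoff >= nyq) stop("cutoff must be below Nyquist")
    lp <- signal::butter(4, cutoff / nyq, type = "low")
    ax <- .filtfiltPad(lp, ax)
  }
  arg <- pmin(pmax(ax / g, -1), 1)
  AngleTrace(90 - acos(arg) * 180 / pi, trace@samplingRate)
}

#' Mean absolute error between two angle traces
#'
#' @param theta,thetaRef [AngleTrace-class] objects (or numeric vectors) of
#'   equal length.
#' @return MAE in degrees.
#' @export
angleError <- function(theta, thetaRef) {
  a <- if (is(theta, "AngleTrace")) theta@theta else as.numeric(theta)
  b <- if (is(thetaRef, "AngleTrace")) thetaRef@theta else as.numeric(thetaRef)
  if (length(a) != length(b)) stop("angle traces must have equal length")
  mean(abs(a - b))
}
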