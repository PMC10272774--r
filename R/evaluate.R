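## Accuracy and cross-day stability metrics.

#' Pearson correlation coefficient
#'
#' Standard centered product-moment correlation between two equal-length
#' series; the package's accuracy and stability metric. Errors on constant
#' input, where the coefficient is undefined.
#'
#' @param x,y numeric vectors (or [AngleTrace-class] objects) of equal
#'   length >= 2.
#' @return correlation in [-1, 1].
#' @examples
#' pearsonCC(1:4, c(1, 2, 3, 5))
#' @export
pearsonCC <- function(x, y) {
  if (is(x, "AngleTrace")) x <- x@theta
  if (is(y, "AngleTrace")) y <- y@theta
  if (length(x) != length(y)) stop("series must have equal length")
  if (length(x) < 2L) stop("series must have length >= 2")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for constant input")
  cor(x, y)
}

#' Cross-run / cross-day synergy stability
#'
#' For every unordered pair of decompositions, matches synergy columns
#' greedily by correlation (see [matchSynergies()]), averages the matched
#' correlations within the pair, then aggregates over pairs. A perfectly
#' repeatable method gives mean 1, sd 0, regardless of column order or
#' positive column scaling.
#'
#' @param decomps list of [SynergyDecomposition-class] objects sharing the
#'   channel count and synergy count.
#' @return list with `pairCC` (per-pair mean matched correlation), `mean`,
#'   `sd`, and the `method` tag of the first decomposition.
#' @export
synergyStability <- function(decomps) {
  stopifnot(length(decomps) >= 2L)
  r <- decomps[[1]]@r
  m <- nrow(decomps[[1]]@C)
  for (d in decomps)
    if (d@r != r || nrow(d@C) != m)
      stop("all decompositions must share channel and synergy counts")
  pairCC <- numeric(0)
  np <- length(decomps)
  for (i in seq_len(np - 1L)) for (j in seq(i + 1L, np)) {
    mt <- matchSynergies(decomps[[i]], decomps[[j]])
    pairCC <- c(pairCC, mean(mt$cc))
  }
  list(method = decomps[[1]]@method, pairCC = pairCC,
       mean = mean(pairCC), sd = if (length(pairCC) > 1L) sd(pairCC) else 0)
}

#' Per-day prediction accuracy report
#'
#' Computes the correlation and the mean absolute error between predicted and
#' measured angle for each day, plus the mean +/- sd aggregation over days.
#'
#' @param pred,actual aligned angle series ([AngleTrace-class] or numeric).
#' @param day integer/factor of the same length labelling each sample's day.
#' @return list with `perDay` (data.frame: day, cc, mae, n) and the
#'   aggregates `ccMean`, `ccSd`, `maeMean`, `maeSd`.
#' @export
accuracyReport <- function(pred, actual, day) {
  if (is(pred, "AngleTrace")) pred <- pred@theta
  if (is(actual, "AngleTrace")) actual <- actual@theta
  if (length(pred) != length(actual) || length(pred) != length(day))
    stop("pred, actual and day must be aligned")
  days <- sort(unique(day))
  perDay <- data.frame(day = days, cc = NA_real_, mae = NA_real_,
                       n = NA_integer_)
  for (i in seq_along(days)) {
    sel <- day == days[i]
    perDay$cc[i] <- pearsonCC(pred[sel], actual[sel])
    perDay$mae[i] <- mean(abs(pred[sel] - actual[sel]))
    perDay$n[i] <- sum(sel)
  }
  list(perDay = perDay,
       ccMean = mean(perDay$cc),
       ccSd = if (nrow(perDay) > 1L) sd(perDay$cc) else 0,
       maeMean = mean(perDay$mae),
       maeSd = if (nrow(perDay) > 1L) sd(perDay$mae) else 0)
}
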