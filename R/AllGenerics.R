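#' Accessors for synergykit classes
#'
#' Small accessor generics so user code never reaches into slots:
#' `envValues` returns the channels x samples envelope matrix, `samplingRate`
#' the sampling rate in Hz, `channelNames` the channel labels,
#' `synergyWeights` the C matrix, `activations` the S matrix,
#' `extractionMethod` the method tag, `objectiveTrace` the per-iteration
#' objective values, `decompositionVAF` the recorded VAF, and `angleValues`
#' the angle series in degrees.
#'
#' @param x a synergykit object.
#' @return the slot contents described above.
#' @name accessors
#' @aliases envValues samplingRate channelNames synergyWeights activations
#'   extractionMethod objectiveTrace decompositionVAF angleValues
NULL

#' @rdname accessors
#' @export
setGeneric("envValues", function(x) standardGeneric("envValues"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("synergyWeights", function(x) standardGeneric("synergyWeights"))
#' @rdname accessors
#' @export
setGeneric("activations", function(x) standardGeneric("activations"))
#' @rdname accessors
#' @export
setGeneric("extractionMethod", function(x) standardGeneric("extractionMethod"))
#' @rdname accessors
#' @export
setGeneric("objectiveTrace", function(x) standardGeneric("objectiveTrace"))
#' @rdname accessors
#' @export
setGeneric("decompositionVAF", function(x) standardGeneric("decompositionVAF"))
#' @rdname accessors
#' @export
setGeneric("angleValues", function(x) standardGeneric("angleValues"))

#' @rdname accessors
setMethod("envValues", "EnvelopeMatrix", function(x) x@values)
#' @rdname accessors
setMethod("samplingRate", "EnvelopeMatrix", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "AccelTrace", function(x) x@samplingRate)
#' @rdname accessors
setMethod("samplingRate", "AngleTrace", function(x) x@samplingRate)
#' @rdname accessors
setMethod("channelNames", "EnvelopeMatrix", function(x) x@channelNames)
#' @rdname accessors
setMethod("synergyWeights", "SynergyDecomposition", function(x) x@C)
#' @rdname accessors
setMethod("activations", "SynergyDecomposition", function(x) x@S)
#' @rdname accessors
setMethod("extractionMethod", "SynergyDecomposition", function(x) x@method)
#' @rdname accessors
setMethod("objectiveTrace", "SynergyDecomposition", function(x) x@objectiveTrace)
#' @rdname accessors
setMethod("decompositionVAF", "SynergyDecomposition", function(x) x@vaf)
#' @rdname accessors
setMethod("angleValues", "AngleTrace", function(x) x@theta)

#' @describeIn EnvelopeMatrix-class matrix dimensions (channels, samples).
#' @param x an EnvelopeMatrix.
#' @export
setMethod("dim", "EnvelopeMatrix", function(x) dim(x@values))

setMethod("show", "EnvelopeMatrix", function(object) {
  d <- dim(object@values)
  cat(sprintf("EnvelopeMatrix: %d channels x %d samples @ %g Hz\n",
              d[1], d[2], object@samplingRate))
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
})

setMethod("show", "SynergyDecomposition", function(object) {
  cat(sprintf("SynergyDecomposition (%s): r = %d, %d channels, %d samples\n",
              object@method, object@r, nrow(object@C), ncol(object@S)))
  cat(sprintf("  iterations: %d, VAF = %.6f\n", object@nIter, object@vaf))
})

setMethod("show", "AccelTrace", function(object) {
  cat(sprintf("AccelTrace: %d samples @ %g Hz, gRef = %s\n",
              length(object@ax), object@samplingRate,
              ifelse(is.na(object@gRef), "uncalibrated",
                     format(object@gRef))))
})

setMethod("show", "AngleTrace", function(object) {
  cat(sprintf("AngleTrace: %d samples @ %g Hz, range [%.2f, %.2f] deg\n",
              length(object@theta), object@samplingRate,
              min(object@theta), max(object@theta)))
})

setMethod("show", "SessionSet", function(object) {
  n <- length(object@recordings)
  subs <- unique(vapply(object@recordings, function(r) r$subject, 1L))
  days <- unique(vapply(object@recordings, function(r) r$day, 1L))
  cat(sprintf("SessionSet: %d recordings, %d subjects, days %s\n",
              n, length(subs), paste(range(days), collapse = "-")))
})

setMethod("show", "AngleRegressor", function(object) {
  cfg <- object@config
  cat(sprintf(
    "AngleRegressor: %d Bi-LSTM layers x %d units/direction, dropout %.2f\n",
    cfg$nLayers, cfg$hiddenUnits, cfg$dropout))
  cat(sprintf("  feature dim %d, trained %d epochs, final loss %.6g\n",
              object@featureDim, length(object@trainingLog),
              if (length(object@trainingLog)) utils::tail(object@trainingLog, 1)
              else NA_real_))
})

setMethod("show", "PurityState", function(object) {
  cat(sprintf("PurityState: %d pure variables selected (alpha = %.3f)\n",
              length(object@selected), object@alpha))
  cat("  selected columns:", paste(object@selected, collapse = ", "), "\n")
})
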