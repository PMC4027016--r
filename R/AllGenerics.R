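#' @rdname AudioSignal-class
#' @param object,x An object.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname AudioSignal-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname AudioSignal-class
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname WaveletPacketTree-class
#' @export
setGeneric("nodeCoefficients", function(x, level, index)
  standardGeneric("nodeCoefficients"))

#' @rdname DimensionFit-class
#' @export
setGeneric("dimensionSlope", function(x) standardGeneric("dimensionSlope"))

#' @describeIn AudioSignal-class Waveform amplitudes.
setMethod("samples", "AudioSignal", function(x) x@samples)

#' @describeIn AudioSignal-class Sampling rate in Hz.
setMethod("samplingRate", "AudioSignal", function(x) x@samplingRate)

#' @describeIn AudioSignal-class Subject identifier.
setMethod("subjectId", "AudioSignal", function(x) x@subjectId)

#' @describeIn AudioSignal-class Number of samples.
setMethod("length", "AudioSignal", function(x) length(x@samples))

setMethod("show", "AudioSignal", function(object) {
  cat(sprintf(
    "AudioSignal: %d samples @ %g Hz (%.3f s)\n",
    length(object@samples), object@samplingRate,
    length(object@samples) / object@samplingRate
  ))
  meta <- c(id = object@subjectId, group = object@group, sex = object@sex,
            age = if (is.na(object@age)) NA_character_ else
              format(object@age))
  meta <- meta[!is.na(meta)]
  if (length(meta))
    cat("  ", paste(names(meta), meta, sep = "=", collapse = " "), "\n")
})

#' @describeIn WaveletPacketTree-class Coefficients of the node at
#'   `(level, index)` with `index` frequency-ordered in
#'   `0:(2^level - 1)`.
#' @param level Decomposition level.
#' @param index Frequency-ordered node index, `0`-based.
setMethod("nodeCoefficients", "WaveletPacketTree",
  function(x, level, index) {
    .checkNode(x, level, index)
    if (level == 0L) return(x@original)
    x@nodes[[level]][[index + 1L]]
  })

setMethod("show", "WaveletPacketTree", function(object) {
  cat(sprintf(
    "WaveletPacketTree: %s, levels 1-%d, input %d samples @ %g Hz\n",
    object@waveletName, object@maxLevel, object@originalLength,
    object@samplingRate
  ))
  cat(sprintf("  level %d: %d nodes x %d coefficients\n",
              object@maxLevel, 2^object@maxLevel,
              object@lengths[object@maxLevel + 1L]))
})

#' @describeIn DimensionFit-class The fitted slope `D_B`.
setMethod("dimensionSlope", "DimensionFit", function(x) x@slope)

setMethod("show", "DimensionFit", function(object) {
  cat(sprintf("DimensionFit: D_B = %.4f (intercept %.3f, R^2 %.4f, %d scales)\n",
              object@slope, object@intercept, object@rSquared,
              nrow(object@points)))
})

setMethod("show", "BoxCountCurve", function(object) {
  cat("BoxCountCurve:\n")
  print(data.frame(scale = object@scales, count = object@counts),
        row.names = FALSE)
})

setMethod("show", "SubbandStats", function(object) {
  sig <- significantNodes(object)
  cat(sprintf(
    "SubbandStats (%s subjects, alpha = %g): %d nodes, %d with >=1 significant pair\n",
    object@stratum, object@alpha, nrow(object@table), nrow(sig)
  ))
})

setMethod("show", "PairwiseSVM", function(object) {
  cat(sprintf("PairwiseSVM: %d classes (%s), %d binary RBF classifiers\n",
              length(object@classes),
              paste(object@classes, collapse = ", "),
              length(object@classifiers)))
  for (cl in object@classifiers)
    cat(sprintf("  %s vs %s: %d features, C = %g, gamma = %g\n",
                cl$pair[1], cl$pair[2], length(cl$features),
                cl$cost, cl$gamma))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: overall accuracy %.2f%% (n = %d, seed %d)\n",
              object@overall, length(object@truth), object@seed))
  for (g in names(object@perGroup))
    cat(sprintf("  group %s: %6.2f%%  (n = %d)\n", g, object@perGroup[g],
                object@counts[g]))
})
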