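#' @import methods
#' @importFrom stats coef lm pt rnorm sd setNames var vcov predict
#' @importFrom utils read.csv write.csv head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame
NULL

.GROUPS <- c("Q", "Y", "H")
.SEXES <- c("male", "female")

#' Sampled vowel waveform with subject metadata
#'
#' `AudioSignal` holds a mono, real-valued waveform together with its
#' sampling rate and optional subject metadata (id, diagnostic group,
#' sex, age).  Amplitudes are dimensionless and expected in `[-1, 1]`
#' when read from PCM audio.
#'
#' @slot samples Numeric vector of amplitudes.
#' @slot samplingRate Sampling rate in Hz.
#' @slot subjectId Subject identifier (may be `NA`).
#' @slot group Diagnostic group, one of `"Q"`, `"Y"`, `"H"`, or `NA`.
#' @slot sex `"male"`, `"female"`, or `NA`.
#' @slot age Age in years, or `NA`.
#'
#' @examples
#' sig <- AudioSignal(sin(2 * pi * 100 * seq(0, 1, length.out = 16000)),
#'                    samplingRate = 16000)
#' sig
#' @exportClass AudioSignal
.AudioSignal <- setClass("AudioSignal",
  slots = c(
    samples = "numeric",
    samplingRate = "numeric",
    subjectId = "character",
    group = "character",
    sex = "character",
    age = "numeric"
  ),
  prototype = list(
    subjectId = NA_character_,
    group = NA_character_,
    sex = NA_character_,
    age = NA_real_
  )
)

setValidity("AudioSignal", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(object@samples) < 1L)
    msg <- c(msg, "samples must contain at least one value")
  if (!all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (!is.na(object@group) && !object@group %in% .GROUPS)
    msg <- c(msg, "group must be one of Q, Y, H or NA")
  if (!is.na(object@sex) && !object@sex %in% .SEXES)
    msg <- c(msg, "sex must be 'male', 'female' or NA")
  if (!is.na(object@age) && object@age < 0)
    msg <- c(msg, "age must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @rdname AudioSignal-class
#' @param samples Numeric amplitude vector.
#' @param samplingRate Sampling rate in Hz.
#' @param subjectId,group,sex,age Optional subject metadata.
#' @export
AudioSignal <- function(samples, samplingRate, subjectId = NA_character_,
                        group = NA_character_, sex = NA_character_,
                        age = NA_real_) {
  .AudioSignal(samples = as.numeric(samples),
               samplingRate = as.numeric(samplingRate),
               subjectId = as.character(subjectId),
               group = as.character(group), sex = as.character(sex),
               age = as.numeric(age))
}

#' Wavelet packet decomposition tree
#'
#' Coefficient sequences of a full wavelet packet decomposition, stored
#' per level in frequency (sequency) order: at level `i` node `n`
#' covers the band `[n * df, (n + 1) * df)` Hz with
#' `df = samplingRate / 2^(i + 1)`.  Natural (Paley) filter-bank order
#' is permuted internally via the Gray code so that public indices are
#' always frequency-ordered.
#'
#' @slot waveletName Wavelet identifier, e.g. `"db4"`.
#' @slot maxLevel Depth of the decomposition.
#' @slot nodes List of levels; `nodes[[i]]` is a list of `2^i`
#'   coefficient vectors in frequency order.
#' @slot lengths Integer vector of coefficient lengths per level
#'   (element 1 is the original signal length).
#' @slot originalLength Length of the analyzed signal.
#' @slot original The analyzed samples (kept for level-0 access and
#'   reconstruction checks).
#' @slot samplingRate Sampling rate in Hz of the analyzed signal.
#'
#' @seealso [wpDecompose()], [reconstructNode()], [nodeFrequencyBand()]
#' @export
#' @exportClass WaveletPacketTree
WaveletPacketTree <- setClass("WaveletPacketTree",
  slots = c(
    waveletName = "character",
    maxLevel = "integer",
    nodes = "list",
    lengths = "integer",
    originalLength = "integer",
    original = "numeric",
    samplingRate = "numeric"
  )
)

setValidity("WaveletPacketTree", function(object) {
  msg <- character()
  if (object@maxLevel < 0L)
    msg <- c(msg, "maxLevel must be >= 0")
  if (length(object@nodes) != object@maxLevel)
    msg <- c(msg, "nodes must hold one list per level")
  for (i in seq_along(object@nodes)) {
    if (length(object@nodes[[i]]) != 2^i) {
      msg <- c(msg, sprintf("level %d must have %d nodes", i, 2^i))
      next
    }
    len <- unique(vapply(object@nodes[[i]], length, integer(1)))
    if (length(len) != 1L)
      msg <- c(msg, sprintf("level %d nodes must share one length", i))
  }
  if (length(msg)) msg else TRUE
})

#' Box-count scaling curve
#'
#' Grid-covering counts `N(s)` of a unit-square-normalized curve at a
#' decreasing sequence of dyadic box sides `s`.
#'
#' @slot scales Strictly decreasing box sides (dimensionless).
#' @slot counts Positive integer covering counts, one per scale.
#' @export
#' @exportClass BoxCountCurve
BoxCountCurve <- setClass("BoxCountCurve",
  slots = c(scales = "numeric", counts = "integer")
)

setValidity("BoxCountCurve", function(object) {
  msg <- character()
  if (length(object@scales) != length(object@counts))
    msg <- c(msg, "scales and counts must have equal length")
  if (any(diff(object@scales) >= 0))
    msg <- c(msg, "scales must be strictly decreasing")
  if (any(object@counts < 1L))
    msg <- c(msg, "counts must be >= 1")
  if (any(object@counts > (1 / object@scales)^2 + 0.5))
    msg <- c(msg, "counts cannot exceed the number of grid cells")
  if (length(msg)) msg else TRUE
})

#' Fitted box dimension
#'
#' Result of the least-squares line fit through
#' `(log(1/s_i), log N(s_i))`: the slope is the box dimension estimate.
#'
#' @slot slope Fitted slope, the box dimension `D_B`.
#' @slot intercept Fitted intercept.
#' @slot rSquared Coefficient of determination of the fit.
#' @slot points Two-column matrix of the fitted `(x, y)` points.
#' @export
#' @exportClass DimensionFit
DimensionFit <- setClass("DimensionFit",
  slots = c(
    slope = "numeric",
    intercept = "numeric",
    rSquared = "numeric",
    points = "matrix"
  )
)

setValidity("DimensionFit", function(object) {
  if (!is.finite(object@slope)) return("slope must be finite")
  TRUE
})

#' Subject-by-subband fractal dimension features
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding the
#' box-dimension feature table: one row per wavelet packet node
#' (default levels 1-5, 62 rows), one column per subject.  `rowData`
#' carries `level`, `index` (frequency-ordered) and the band limits in
#' kHz; `colData` carries `subject_id`, `group`, `sex`, `age`.
#'
#' @export
#' @exportClass FractalFeatureSet
setClass("FractalFeatureSet", contains = "SummarizedExperiment")

setValidity("FractalFeatureSet", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("level", "index") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'level' and 'index'")
  if (!all(c("subject_id", "group", "sex", "age") %in% colnames(cd)))
    msg <- c(msg, "colData must contain subject_id, group, sex, age")
  if (!"dimension" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'dimension' is required")
  if (length(msg)) msg else TRUE
})

#' Per-subband age-adjusted group comparison table
#'
#' One row per wavelet packet node with raw per-group means/SDs of the
#' box dimension and age-adjusted pairwise p-values (`p_HY`, `p_HQ`,
#' `p_YQ`) from a linear model with group and age terms.
#'
#' @slot table `data.frame` with one row per node.
#' @slot stratum `"all"`, `"male"`, or `"female"`.
#' @slot alpha Significance level used for the flag columns.
#' @export
#' @exportClass SubbandStats
SubbandStats <- setClass("SubbandStats",
  slots = c(table = "data.frame", stratum = "character", alpha = "numeric")
)

setValidity("SubbandStats", function(object) {
  msg <- character()
  need <- c("level", "index", "p_HY", "p_HQ", "p_YQ")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, "table must contain level, index and pairwise p columns")
  p <- unlist(object@table[, c("p_HY", "p_HQ", "p_YQ")])
  if (any(p < 0 | p > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (!object@stratum %in% c("all", "male", "female"))
    msg <- c(msg, "stratum must be all, male or female")
  if (length(msg)) msg else TRUE
})

#' One-vs-one multiclass RBF-SVM model
#'
#' `k(k-1)/2` binary radial-basis SVMs, each with its own feature
#' subset (significant subbands for that pair) and grid-searched
#' `(C, gamma)`, combined by majority vote.  Standardization parameters
#' are estimated from training rows only and stored per classifier.
#'
#' @slot classes Class labels (vote tie-break follows this order).
#' @slot classifiers List of per-pair fits: feature names, scaling
#'   center/scale, chosen cost and gamma, and the fitted
#'   [e1071::svm] object.
#' @export
#' @exportClass PairwiseSVM
PairwiseSVM <- setClass("PairwiseSVM",
  slots = c(classes = "character", classifiers = "list")
)

setValidity("PairwiseSVM", function(object) {
  k <- length(object@classes)
  if (length(object@classifiers) != k * (k - 1) / 2)
    return("need k(k-1)/2 binary classifiers")
  TRUE
})

#' Cross-validated classification report
#'
#' Per-group and overall accuracies (percent) from stratified k-fold
#' cross-validation, with fold assignments and the seed used.
#'
#' @slot overall Overall accuracy in percent.
#' @slot perGroup Named numeric vector of per-group accuracies (%).
#' @slot counts Named integer vector of per-group subject counts.
#' @slot folds Integer vector of fold assignments (one per subject).
#' @slot predictions Character vector of out-of-fold predictions.
#' @slot truth Character vector of true labels.
#' @slot seed Seed used for fold assignment and model fitting.
#' @slot details List with per-fold chosen parameters and features.
#' @export
#' @exportClass EvalReport
EvalReport <- setClass("EvalReport",
  slots = c(
    overall = "numeric",
    perGroup = "numeric",
    counts = "integer",
    folds = "integer",
    predictions = "character",
    truth = "character",
    seed = "integer",
    details = "list"
  )
)

setValidity("EvalReport", function(object) {
  msg <- character()
  if (any(object@overall < 0 | object@overall > 100))
    msg <- c(msg, "accuracies must lie in [0, 100]")
  if (any(object@perGroup < 0 | object@perGroup > 100))
    msg <- c(msg, "per-group accuracies must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})
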