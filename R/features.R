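## Wavelet packet fractal dimension features: the box dimension of
## every subband coefficient sequence, assembled per subject.

#' Node labels for a set of levels
#'
#' Feature names follow the `L<level>_n<index>` convention with
#' frequency-ordered indices, e.g. `L3_n4` for the 4-5 kHz band at a
#' 16 kHz sampling rate.
#'
#' @param levels Integer vector of decomposition levels.
#' @return Character vector of labels, level-major order.
#' @export
featureNodeNames <- function(levels = 1:5) {
  unlist(lapply(levels, function(l) sprintf("L%d_n%d", l, 0:(2^l - 1L))))
}

.nodeGrid <- function(levels) {
  do.call(rbind, lapply(levels, function(l)
    data.frame(level = l, index = 0:(2^l - 1L))))
}

#' Extract the wavelet packet fractal dimension vector of one signal
#'
#' Decomposes the signal to `max(levels)` and computes the box
#' dimension of each subband coefficient sequence at the requested
#' levels (default 1-5: 2+4+8+16+32 = 62 features, frequency order).
#' Alternatively the dimension can be computed on the time-domain
#' subband reconstructions.
#'
#' @param signal An [AudioSignal] (or numeric vector with
#'   `samplingRate`).
#' @param levels Levels to extract (subset of 1..7).
#' @param waveletName Wavelet for the decomposition (default `"db4"`).
#' @param onReconstruction If `TRUE`, compute dimensions on
#'   [reconstructNode()] outputs instead of coefficient sequences.
#' @param maxScaleExp Passed to [boxDimension()].
#' @param samplingRate Required when `signal` is a numeric vector.
#' @return Named numeric vector of box dimensions (names from
#'   [featureNodeNames()]).
#' @examples
#' sig <- AudioSignal(sin(2 * pi * 150 * (0:16383) / 16000) +
#'                      0.05 * sin(2 * pi * 4500 * (0:16383) / 16000),
#'                    samplingRate = 16000)
#' fv <- extractFeatures(sig, levels = 1:2)
#' round(fv, 3)
#' @export
extractFeatures <- function(signal, levels = 1:5, waveletName = "db4",
                            onReconstruction = FALSE, maxScaleExp = 8L,
                            samplingRate = NULL) {
  stopifnot(all(levels %in% 1:7), length(levels) >= 1L)
  levels <- sort(unique(as.integer(levels)))
  tree <- wpDecompose(signal, waveletName, max(levels),
                      samplingRate = samplingRate)
  grid <- .nodeGrid(levels)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    seqv <- if (onReconstruction)
      reconstructNode(tree, grid$level[i], grid$index[i])
    else
      tree@nodes[[grid$level[i]]][[grid$index[i] + 1L]]
    .boxDimFast(seqv, maxScaleExp)
  }, numeric(1))
  setNames(vals, featureNodeNames(levels))
}

#' Build the subject-by-subband feature table of a cohort
#'
#' Runs [selectStableSegment()] and [extractFeatures()] on every
#' subject of a cohort and assembles a [FractalFeatureSet]
#' (SummarizedExperiment: rows = subband nodes, columns = subjects).
#'
#' @param cohort Either a `data.frame` manifest with columns
#'   `subject_id, path, group, sex, age` (audio read from `path`), or a
#'   synthetic cohort list as returned by [generateCohort()] (signals
#'   in memory).
#' @param levels,waveletName,onReconstruction,maxScaleExp Passed to
#'   [extractFeatures()].
#' @param segmentDuration Stable-segment length in seconds; `NULL`
#'   skips segmentation (signals used as-is).  Signals shorter than the
#'   requested duration are used whole.
#' @param resampleTo Optional target rate passed to [readAudio()].
#' @return A [FractalFeatureSet] with one column per subject.
#' @export
buildFeatureTable <- function(cohort, levels = 1:5, waveletName = "db4",
                              onReconstruction = FALSE, maxScaleExp = 8L,
                              segmentDuration = 1, resampleTo = NULL) {
  if (is.data.frame(cohort)) {
    manifest <- cohort
    getSignal <- function(i) readAudio(
      manifest$path[i], subjectId = manifest$subject_id[i],
      group = manifest$group[i], sex = manifest$sex[i],
      age = manifest$age[i], resampleTo = resampleTo)
  } else if (is.list(cohort) && !is.null(cohort$manifest) &&
             !is.null(cohort$signals)) {
    manifest <- cohort$manifest
    getSignal <- function(i) cohort$signals[[i]]
  } else {
    stop("cohort must be a manifest data.frame or a generateCohort() result")
  }
  grid <- .nodeGrid(sort(unique(as.integer(levels))))
  nms <- featureNodeNames(sort(unique(as.integer(levels))))
  n <- nrow(manifest)
  mat <- matrix(NA_real_, nrow = length(nms), ncol = n,
                dimnames = list(nms, manifest$subject_id))
  rate <- NA_real_
  for (i in seq_len(n)) {
    sig <- getSignal(i)
    if (!is.null(segmentDuration) &&
        length(sig) > round(segmentDuration * samplingRate(sig)))
      sig <- selectStableSegment(sig, segmentDuration)
    rate <- samplingRate(sig)
    mat[, i] <- extractFeatures(sig, levels = levels,
                                waveletName = waveletName,
                                onReconstruction = onReconstruction,
                                maxScaleExp = maxScaleExp)
  }
  bands <- if (is.finite(rate))
    t(vapply(seq_len(nrow(grid)), function(i)
      nodeFrequencyBand(grid$level[i], grid$index[i], rate) / 1000,
      numeric(2)))
  else
    matrix(NA_real_, nrow(grid), 2)
  rowDat <- S4Vectors::DataFrame(
    level = grid$level, index = grid$index,
    low_khz = bands[, 1L], high_khz = bands[, 2L], row.names = nms)
  colDat <- S4Vectors::DataFrame(
    subject_id = manifest$subject_id,
    group = manifest$group, sex = manifest$sex, age = manifest$age,
    row.names = manifest$subject_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dimension = mat), rowData = rowDat, colData = colDat)
  methods::new("FractalFeatureSet", se)
}

#' Construct a feature set from a matrix
#'
#' Low-level constructor used when features come from elsewhere than
#' [buildFeatureTable()] (simulations, external tables).
#'
#' @param dimensions Numeric matrix, nodes x subjects; row names of
#'   the `L<level>_n<index>` form (defaults to
#'   [featureNodeNames()] for the matching level set).
#' @param meta `data.frame` with columns `subject_id`, `group`, `sex`,
#'   `age`, one row per subject.
#' @param samplingRate Rate used to annotate band limits.
#' @return A [FractalFeatureSet].
#' @export
fractalFeatureSet <- function(dimensions, meta, samplingRate = 16000) {
  if (is.null(rownames(dimensions))) {
    lv <- if (nrow(dimensions) == 62L) 1:5 else
      stop("dimensions without rownames must have 62 rows (levels 1-5)")
    rownames(dimensions) <- featureNodeNames(lv)
  }
  parsed <- regmatches(rownames(dimensions),
                       regexec("^L([0-9]+)_n([0-9]+)$",
                               rownames(dimensions)))
  if (any(vapply(parsed, length, integer(1)) != 3L))
    stop("rownames must be of the form L<level>_n<index>")
  level <- as.integer(vapply(parsed, `[`, character(1), 2L))
  index <- as.integer(vapply(parsed, `[`, character(1), 3L))
  bands <- t(mapply(nodeFrequencyBand, level, index,
                    MoreArgs = list(samplingRate = samplingRate))) / 1000
  colnames(dimensions) <- meta$subject_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dimension = dimensions),
    rowData = S4Vectors::DataFrame(level = level, index = index,
                                   low_khz = bands[, 1L],
                                   high_khz = bands[, 2L],
                                   row.names = rownames(dimensions)),
    colData = S4Vectors::DataFrame(subject_id = meta$subject_id,
                                   group = meta$group, sex = meta$sex,
                                   age = meta$age,
                                   row.names = meta$subject_id))
  methods::new("FractalFeatureSet", se)
}

#' Write / read a feature table as CSV
#'
#' The CSV dialect is one row per subject:
#' `subject_id,group,sex,age,L1_n0,...` so tables can be inspected and
#' exchanged with other tools.
#'
#' @param ffs A [FractalFeatureSet].
#' @param path Output (input) CSV path.
#' @return `writeFeatureCSV`: `path` invisibly; `readFeatureCSV`: a
#'   [FractalFeatureSet].
#' @export
writeFeatureCSV <- function(ffs, path) {
  mat <- SummarizedExperiment::assay(ffs, "dimension")
  cd <- as.data.frame(SummarizedExperiment::colData(ffs))
  out <- cbind(cd[, c("subject_id", "group", "sex", "age")],
               as.data.frame(t(mat)))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeFeatureCSV
#' @param samplingRate Sampling rate (Hz) used to annotate band limits
#'   when reading (default 16000).
#' @export
readFeatureCSV <- function(path, samplingRate = 16000) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  meta <- c("subject_id", "group", "sex", "age")
  if (!all(meta %in% colnames(d)))
    stop("feature CSV must start with columns: ",
         paste(meta, collapse = ", "))
  featCols <- setdiff(colnames(d), meta)
  parsed <- regmatches(featCols, regexec("^L([0-9]+)_n([0-9]+)$", featCols))
  if (any(vapply(parsed, length, integer(1)) != 3L))
    stop("feature columns must be named L<level>_n<index>")
  grid <- data.frame(
    level = as.integer(vapply(parsed, `[`, character(1), 2L)),
    index = as.integer(vapply(parsed, `[`, character(1), 3L)))
  mat <- t(as.matrix(d[, featCols, drop = FALSE]))
  colnames(mat) <- d$subject_id
  bands <- t(mapply(nodeFrequencyBand, grid$level, grid$index,
                    MoreArgs = list(samplingRate = samplingRate))) / 1000
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(dimension = mat),
    rowData = S4Vectors::DataFrame(level = grid$level, index = grid$index,
                                   low_khz = bands[, 1L],
                                   high_khz = bands[, 2L],
                                   row.names = featCols),
    colData = S4Vectors::DataFrame(subject_id = d$subject_id,
                                   group = d$group, sex = d$sex,
                                   age = d$age, row.names = d$subject_id))
  methods::new("FractalFeatureSet", se)
}
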