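## One-vs-one multiclass RBF-SVM with per-pair feature subsets and
## per-pair grid-searched kernel parameters (libsvm via e1071).

#' Default libsvm-style hyperparameter grid
#'
#' `C` on `2^(-5), 2^(-3), ..., 2^15` and `gamma` on
#' `2^(-15), ..., 2^3` (steps of `2^2`).
#'
#' @return List with numeric vectors `cost` and `gamma`.
#' @export
defaultSvmGrid <- function() {
  list(cost = 2^seq(-5, 15, by = 2), gamma = 2^seq(-15, 3, by = 2))
}

## deterministic local RNG: run fn under seed, restore global state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## stratified fold assignment: shuffle within class, deal round-robin
.stratifiedFolds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Grid search for RBF-SVM hyperparameters
#'
#' Selects `(C, gamma)` maximizing stratified inner-cross-validation
#' accuracy; ties are broken toward smaller `C`, then smaller `gamma`.
#'
#' @param x Numeric feature matrix (subjects x features).
#' @param y Class labels (coerced to factor).
#' @param grid List with `cost` and `gamma` vectors (default
#'   [defaultSvmGrid()]).
#' @param innerFolds Number of inner CV folds (default 5; capped at
#'   the smallest class size).
#' @param seed Seed for the fold assignment.
#' @return List with `cost`, `gamma`, and the achieved `accuracy`.
#' @export
gridSearchRbf <- function(x, y, grid = defaultSvmGrid(), innerFolds = 5L,
                          seed = 1L) {
  y <- factor(y)
  if (nlevels(y) < 2L) stop("need at least 2 classes")
  minClass <- min(table(y))
  if (minClass < 2L)
    stop("a class has fewer than 2 members; cannot stratify inner folds")
  k <- min(as.integer(innerFolds), minClass)
  if (k < 2L) stop("innerFolds must be >= 2")
  fold <- .withSeed(seed, function() .stratifiedFolds(y, k))
  params <- expand.grid(gamma = sort(grid$gamma), cost = sort(grid$cost))
  params <- params[order(params$cost, params$gamma), ]
  best <- list(cost = NA_real_, gamma = NA_real_, accuracy = -1)
  for (i in seq_len(nrow(params))) {
    correct <- 0L
    for (f in seq_len(k)) {
      tr <- fold != f
      fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "radial",
                        cost = params$cost[i], gamma = params$gamma[i],
                        scale = FALSE)
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    acc <- correct / length(y)
    if (acc > best$accuracy + 1e-12) {
      best <- list(cost = params$cost[i], gamma = params$gamma[i],
                   accuracy = acc)
    }
  }
  best
}

.pairGroups <- function(pair) {
  c(substr(pair, 1L, 1L), substr(pair, 2L, 2L))
}

#' Train the one-vs-one multiclass model
#'
#' For each group pair: restrict to that pair's subjects, select the
#' pair's discriminative subbands from an age-adjusted significance
#' table computed on the training rows only (unless a precomputed
#' table is supplied), z-score the features with training parameters,
#' grid-search `(C, gamma)`, and fit the binary RBF-SVM.  If a pair has
#' no significant subband at `alpha`, all features are used (with a
#' message).
#'
#' @param ffs Training [FractalFeatureSet]; all three groups must be
#'   present.
#' @param alpha Feature-selection significance level.
#' @param grid,innerFolds Passed to [gridSearchRbf()].
#' @param seed Seed controlling inner fold assignment.
#' @param stats Optional precomputed [SubbandStats] used for feature
#'   selection (whole-dataset selection reproduces the original
#'   select-then-validate ordering; the default, `NULL`, recomputes on
#'   the training rows to avoid selection leakage).
#' @param adjustAge Use the age covariate during feature selection.
#' @return A [PairwiseSVM].
#' @export
trainOneVsOne <- function(ffs, alpha = 0.05, grid = defaultSvmGrid(),
                          innerFolds = 5L, seed = 1L, stats = NULL,
                          adjustAge = TRUE) {
  cd <- SummarizedExperiment::colData(ffs)
  if (!all(.GROUPS %in% cd$group))
    stop("all three groups must be present in the training data")
  if (is.null(stats))
    stats <- significanceTable(ffs, "all", alpha = alpha,
                               adjustAge = adjustAge)
  mat <- t(SummarizedExperiment::assay(ffs, "dimension"))
  classifiers <- list()
  for (pair in .PAIRS) {
    gp <- .pairGroups(pair)
    rows <- cd$group %in% gp
    feats <- selectDiscriminative(stats, pair, alpha)
    if (length(feats) == 0L) {
      message("pair ", pair, ": no significant subband at alpha = ",
              alpha, "; falling back to all ", ncol(mat), " features")
      feats <- colnames(mat)
    }
    xm <- mat[rows, feats, drop = FALSE]
    center <- colMeans(xm)
    scl <- apply(xm, 2, sd)
    scl[scl == 0] <- 1
    xs <- scale(xm, center, scl)
    y <- factor(cd$group[rows], levels = gp)
    sel <- gridSearchRbf(xs, y, grid, innerFolds, seed)
    fit <- e1071::svm(xs, y, kernel = "radial", cost = sel$cost,
                      gamma = sel$gamma, scale = FALSE)
    classifiers[[pair]] <- list(pair = gp, features = feats,
                                center = center, scale = scl,
                                cost = sel$cost, gamma = sel$gamma,
                                innerAccuracy = sel$accuracy, fit = fit)
  }
  PairwiseSVM(classes = .GROUPS, classifiers = classifiers)
}

#' Predict group labels with a one-vs-one model
#'
#' Majority vote over the pairwise decisions; ties are broken by the
#' largest summed absolute decision value, then by the fixed class
#' order of `model@classes`.
#'
#' @param model A [PairwiseSVM].
#' @param newdata Feature matrix (subjects x features) or a
#'   [FractalFeatureSet]; columns must include every feature used by
#'   the model.
#' @return Character vector of predicted group labels.
#' @export
predictGroups <- function(model, newdata) {
  if (is(newdata, "FractalFeatureSet"))
    newdata <- t(SummarizedExperiment::assay(newdata, "dimension"))
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1,
                                               dimnames = list(NULL,
                                                 names(newdata)))
  n <- nrow(newdata)
  votes <- matrix(0L, n, length(model@classes),
                  dimnames = list(NULL, model@classes))
  for (cl in model@classifiers) {
    miss <- setdiff(cl$features, colnames(newdata))
    if (length(miss))
      stop("newdata lacks model features: ", paste(head(miss), collapse = ", "))
    xs <- scale(newdata[, cl$features, drop = FALSE], cl$center, cl$scale)
    pred <- predict(cl$fit, xs)
    ci <- match(as.character(pred), model@classes)
    idx <- cbind(seq_len(n), ci)
    votes[idx] <- votes[idx] + 1L
  }
  ## per subject: max votes; ties -> re-vote weighted by |decision|
  out <- character(n)
  for (i in seq_len(n)) {
    v <- votes[i, ]
    top <- names(v)[v == max(v)]
    if (length(top) == 1L) {
      out[i] <- top
    } else {
      ## full tie: rank tied classes by their summed |decision values|
      s <- setNames(numeric(length(top)), top)
      for (cl in model@classifiers) {
        if (!all(cl$pair %in% top)) next
        xs <- scale(newdata[i, cl$features, drop = FALSE], cl$center,
                    cl$scale)
        pred <- predict(cl$fit, xs, decision.values = TRUE)
        dv <- abs(attr(pred, "decision.values")[1L])
        s[as.character(pred)] <- s[as.character(pred)] + dv
      }
      top <- top[order(-s[top], match(top, model@classes))]
      out[i] <- top[1L]
    }
  }
  out
}

#' Stratified k-fold cross-validation of the full pipeline
#'
#' Per outer fold the complete training pipeline runs on the training
#' rows only (significance-based feature selection, standardization,
#' nested grid search, SVM fitting); out-of-fold predictions are
#' aggregated into per-group and overall accuracies.
#'
#' @param ffs A [FractalFeatureSet].
#' @param folds Number of outer folds (default 3).
#' @param seed Seed for fold assignment and nested searches.
#' @param alpha,grid,innerFolds,adjustAge Passed to [trainOneVsOne()].
#' @param globalSelection If `TRUE`, feature selection uses a significance
#'   table computed once on the full dataset (select-then-validate
#'   ordering) instead of per-fold training rows.
#' @return An [EvalReport].
#' @export
crossValidate <- function(ffs, folds = 3L, seed = 1L, alpha = 0.05,
                          grid = defaultSvmGrid(), innerFolds = 5L,
                          adjustAge = TRUE, globalSelection = FALSE) {
  cd <- SummarizedExperiment::colData(ffs)
  labels <- cd$group
  if (min(table(labels)) < folds)
    stop("each class needs at least `folds` members to stratify")
  fold <- .withSeed(seed, function() .stratifiedFolds(labels, folds))
  fullStats <- if (globalSelection)
    significanceTable(ffs, "all", alpha = alpha, adjustAge = adjustAge)
  else NULL
  preds <- character(length(labels))
  details <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    model <- trainOneVsOne(ffs[, tr], alpha = alpha, grid = grid,
                           innerFolds = innerFolds,
                           seed = seed + f, stats = fullStats,
                           adjustAge = adjustAge)
    preds[!tr] <- predictGroups(
      model, t(SummarizedExperiment::assay(ffs, "dimension")[, !tr,
                                                             drop = FALSE]))
    details[[f]] <- lapply(model@classifiers, function(cl)
      list(features = cl$features, cost = cl$cost, gamma = cl$gamma))
  }
  counts <- table(factor(labels, levels = .GROUPS))
  perGroup <- vapply(.GROUPS, function(g)
    100 * mean(preds[labels == g] == g), numeric(1))
  EvalReport(
    overall = 100 * mean(preds == labels),
    perGroup = perGroup,
    counts = setNames(as.integer(counts), names(counts)),
    folds = fold, predictions = preds, truth = as.character(labels),
    seed = as.integer(seed), details = details)
}

#' Combine stratum accuracies into a weighted accuracy
#'
#' `sum(acc_s * n_s) / sum(n_s)`, the overall accuracy when strata are
#' modelled separately, reported to 2 decimals.
#'
#' @param accuracies Named numeric vector of stratum accuracies in
#'   percent.
#' @param counts Named integer vector of stratum sizes (same names).
#' @return Weighted accuracy in percent, rounded to 2 decimals.
#' @examples
#' weightedAccuracy(c(male = 72.07, female = 91.95),
#'                  c(male = 68, female = 161))
#' @export
weightedAccuracy <- function(accuracies, counts) {
  if (!setequal(names(accuracies), names(counts)) ||
      is.null(names(accuracies)))
    stop("accuracies and counts must share the same stratum names")
  counts <- counts[names(accuracies)]
  if (any(counts <= 0)) stop("counts must be positive")
  round(sum(accuracies * counts) / sum(counts), 2)
}

#' Cross-validate separate per-sex models
#'
#' Trains and evaluates fully separate male and female models (the
#' sex-stratified design) and combines their overall accuracies with
#' [weightedAccuracy()].
#'
#' @inheritParams crossValidate
#' @return List with elements `male`, `female` (both [EvalReport]) and
#'   `weighted` (percent).
#' @export
crossValidateBySex <- function(ffs, folds = 3L, seed = 1L, alpha = 0.05,
                               grid = defaultSvmGrid(), innerFolds = 5L,
                               adjustAge = TRUE, globalSelection = FALSE) {
  cd <- SummarizedExperiment::colData(ffs)
  reports <- lapply(setNames(.SEXES, .SEXES), function(s)
    crossValidate(ffs[, cd$sex == s], folds = folds, seed = seed,
                  alpha = alpha, grid = grid, innerFolds = innerFolds,
                  adjustAge = adjustAge, globalSelection = globalSelection))
  n <- vapply(.SEXES, function(s) sum(cd$sex == s), numeric(1))
  list(male = reports$male, female = reports$female,
       weighted = weightedAccuracy(
         vapply(reports, function(r) r@overall, numeric(1)), n))
}
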