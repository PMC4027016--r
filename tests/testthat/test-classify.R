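test_that("grid search finds separating parameters and is deterministic", {
  set.seed(1)
  x <- rbind(matrix(rnorm(40, 0), 20), matrix(rnorm(40, 4), 20))
  y <- rep(c("a", "b"), each = 20)
  sel <- gridSearchRbf(x, y, seed = 3)
  expect_equal(sel$accuracy, 1)
  expect_identical(sel, gridSearchRbf(x, y, seed = 3))
  ## one-point grid returns that point
  one <- gridSearchRbf(x, y, grid = list(cost = 2, gamma = 0.5))
  expect_equal(one$cost, 2)
  expect_equal(one$gamma, 0.5)
  ## ties break toward smaller cost then gamma: a duplicate grid
  dup <- gridSearchRbf(x, y, grid = list(cost = c(8, 2), gamma = c(1, 0.1)))
  expect_equal(dup$cost, 2)
  expect_equal(dup$gamma, 0.1)
  expect_error(gridSearchRbf(x, rep("a", 40)), "2 classes")
})

test_that("one-vs-one training builds k(k-1)/2 per-pair classifiers", {
  ffs <- gaussianFeatureSet(shift = 3)
  model <- trainOneVsOne(ffs, grid = smallSvmGrid(), seed = 2)
  expect_s4_class(model, "PairwiseSVM")
  expect_length(model@classifiers, 3L)         # k = 3
  expect_setequal(names(model@classifiers), c("HY", "HQ", "YQ"))
  ## the contract k(k-1)/2 is enforced structurally
  expect_error(PairwiseSVM(classes = c("a", "b", "c", "d"),
                           classifiers = model@classifiers),
               "k\\(k-1\\)/2")
  expect_true(validObject(PairwiseSVM(classes = c("a", "b"),
                                      classifiers = model@classifiers[1])))
  ## separable training data is memorized
  preds <- predictGroups(model, ffs)
  expect_gte(mean(preds == SummarizedExperiment::colData(ffs)$group),
             0.95)
  ## deterministic retraining
  model2 <- trainOneVsOne(ffs, grid = smallSvmGrid(), seed = 2)
  for (p in names(model@classifiers)) {
    expect_identical(model@classifiers[[p]]$cost,
                     model2@classifiers[[p]]$cost)
    expect_identical(model@classifiers[[p]]$features,
                     model2@classifiers[[p]]$features)
  }
})

test_that("prediction is invariant to features outside the model subsets", {
  ffs <- gaussianFeatureSet(shift = 3)
  model <- trainOneVsOne(ffs, grid = smallSvmGrid(), seed = 2)
  used <- unique(unlist(lapply(model@classifiers, `[[`, "features")))
  mat <- t(SummarizedExperiment::assay(ffs, "dimension"))
  pred1 <- predictGroups(model, mat)
  mat2 <- mat
  unused <- setdiff(colnames(mat), used)
  if (length(unused))
    mat2[, unused] <- mat2[, unused] + 100
  expect_identical(pred1, predictGroups(model, mat2))
  expect_error(predictGroups(model, mat[, 1:3]), "lacks")
})

test_that("weighted accuracy is the count-weighted mean of strata", {
  expect_equal(weightedAccuracy(c(male = 72.07, female = 91.95),
                                c(male = 68, female = 161)), 86.05)
  expect_equal(weightedAccuracy(c(a = 80, b = 80), c(a = 7, b = 193)), 80)
  expect_equal(weightedAccuracy(c(a = 100, b = 0), c(a = 1, b = 3)), 25)
  expect_error(weightedAccuracy(c(a = 50), c(b = 10)), "names")
})

test_that("cross-validation satisfies the accounting identity", {
  ffs <- gaussianFeatureSet(shift = 2.5)
  rep <- crossValidate(ffs, folds = 3, seed = 5, grid = smallSvmGrid())
  counts <- rep@counts
  recombined <- sum(rep@perGroup * counts) / sum(counts)
  expect_equal(rep@overall, recombined, tolerance = 1e-9)
  expect_length(rep@folds, ncol(ffs))
  expect_true(all(table(rep@folds, rep@truth) >= 1))
  ## separable classes are recovered well out of fold
  expect_gte(rep@overall, 80)
})

test_that("fold models ignore their own test rows (no leakage)", {
  ffs <- gaussianFeatureSet(nPer = c(Q = 15, Y = 12, H = 12), shift = 2,
                            seed = 9)
  r1 <- crossValidate(ffs, folds = 3, seed = 4, grid = smallSvmGrid())
  ## corrupt one subject's features; only models of folds trained WITH
  ## that subject may change - its own fold's model must not
  mat <- SummarizedExperiment::assay(ffs, "dimension")
  victim <- 5L
  mat[, victim] <- mat[, victim] + 50
  ffs2 <- fractalFeatureSet(mat, as.data.frame(
    SummarizedExperiment::colData(ffs)))
  r2 <- crossValidate(ffs2, folds = 3, seed = 4, grid = smallSvmGrid())
  f <- r1@folds[victim]
  expect_identical(r1@details[[f]], r2@details[[f]])
})

test_that("label noise degrades out-of-fold accuracy", {
  for (seed in 1:10) {
    ffs <- gaussianFeatureSet(nPer = c(Q = 15, Y = 12, H = 12),
                              shift = 2.5, seed = seed)
    clean <- crossValidate(ffs, folds = 3, seed = seed,
                           grid = smallSvmGrid())
    cd <- as.data.frame(SummarizedExperiment::colData(ffs))
    set.seed(seed)
    flip <- sample(ncol(ffs), round(0.2 * ncol(ffs)))
    cd$group[flip] <- vapply(cd$group[flip], function(g)
      sample(setdiff(c("Q", "Y", "H"), g), 1), character(1))
    noisy <- crossValidate(
      fractalFeatureSet(SummarizedExperiment::assay(ffs, "dimension"),
                        cd),
      folds = 3, seed = seed, grid = smallSvmGrid())
    expect_gte(clean@overall, noisy@overall)
  }
})

test_that("sex-stratified evaluation recombines by subject proportion", {
  ffs <- gaussianFeatureSet(nPer = c(Q = 20, Y = 16, H = 14),
                            shift = 2.5)
  bs <- crossValidateBySex(ffs, folds = 2, seed = 3,
                           grid = smallSvmGrid())
  cd <- SummarizedExperiment::colData(ffs)
  manual <- weightedAccuracy(
    c(male = bs$male@overall, female = bs$female@overall),
    c(male = sum(cd$sex == "male"), female = sum(cd$sex == "female")))
  expect_equal(bs$weighted, manual)
})
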