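simNullNode <- function(n = 50) {
  groups <- rep(c("H", "Y", "Q"), each = n)
  ages <- c(rnorm(n, 26, 6), rnorm(n, 53, 10), rnorm(n, 45, 12))
  list(values = rnorm(3 * n, 1.6, 0.05), groups = groups, ages = ages)
}

test_that("type-I error of the age-adjusted contrasts is calibrated", {
  set.seed(101)
  hits <- 0L
  nSim <- 1000L
  for (i in seq_len(nSim)) {
    d <- simNullNode()
    row <- compareNode(d$values, d$groups, d$ages)
    hits <- hits + sum(row$sig_HY, row$sig_HQ, row$sig_YQ)
  }
  rate <- hits / (3 * nSim)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("a one-pooled-SD group shift is detected with high power", {
  set.seed(202)
  detected <- 0L
  for (i in 1:200) {
    d <- simNullNode()
    d$values[d$groups == "Q"] <- d$values[d$groups == "Q"] + 0.05
    row <- compareNode(d$values, d$groups, d$ages)
    detected <- detected + row$sig_HQ
  }
  expect_gte(detected / 200, 0.95)
})

test_that("age adjustment removes confounding by age structure", {
  ## groups share one age->dimension trend but differ in age
  ## distribution: unadjusted comparisons inflate, adjusted stay flat
  set.seed(303)
  pAdj <- pRaw <- numeric(300)
  for (i in 1:300) {
    groups <- rep(c("H", "Y", "Q"), each = 40)
    ages <- c(rnorm(40, 26, 5), rnorm(40, 54, 5), rnorm(40, 45, 5))
    values <- 1.5 + 0.004 * ages + rnorm(120, 0, 0.04)
    pAdj[i] <- compareNode(values, groups, ages)$p_HY
    pRaw[i] <- compareNode(values, groups, ages,
                           adjustAge = FALSE)$p_HY
  }
  expect_gt(mean(pRaw < 0.05), 0.5)    # confounded test fires
  expect_lt(mean(pAdj < 0.05), 0.12)   # adjusted test stays near alpha
  ## adjusted p-values roughly uniform: mean near 0.5
  expect_gt(mean(pAdj), 0.35)
})

test_that("contrast arithmetic matches the emmeans oracle", {
  set.seed(7)
  d <- simNullNode(20)
  d$values[d$groups == "Q"] <- d$values[d$groups == "Q"] + 0.03
  for (adj in c(TRUE, FALSE)) {
    row <- compareNode(d$values, d$groups, d$ages, adjustAge = adj)
    df <- data.frame(v = d$values, g = factor(d$groups), age = d$ages)
    fit <- if (adj) lm(v ~ g + age, df) else lm(v ~ g, df)
    em <- summary(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                    "pairwise", adjust = "none"))
    getP <- function(a, b)
      em$p.value[em$contrast %in% c(paste(a, "-", b), paste(b, "-", a))]
    expect_equal(row$p_HY, getP("H", "Y"), tolerance = 1e-10)
    expect_equal(row$p_HQ, getP("H", "Q"), tolerance = 1e-10)
    expect_equal(row$p_YQ, getP("Y", "Q"), tolerance = 1e-10)
  }
})

test_that("compareNode enforces its preconditions", {
  expect_error(compareNode(rnorm(10), rep("Q", 10), rnorm(10, 40)),
               "2 groups")
  expect_error(compareNode(rnorm(5), c("Q", "Q", "Q", "Y", "Y"),
                           rnorm(5, 40)), "3 subjects")
  d <- simNullNode(5)
  expect_error(compareNode(d$values, d$groups, rep(NA_real_, 15)),
               "finite")
})

test_that("significance table flags injected group differences", {
  set.seed(55)
  ffs <- gaussianFeatureSet(nPer = c(Q = 30, Y = 20, H = 18), shift = 0)
  mat <- SummarizedExperiment::assay(ffs, "dimension")
  ## inject Q shifts in two nodes only
  qcols <- SummarizedExperiment::colData(ffs)$group == "Q"
  inject <- c("L3_n4", "L4_n8")
  mat[inject, qcols] <- mat[inject, qcols] + 1.5
  ffs2 <- fractalFeatureSet(mat, as.data.frame(
    SummarizedExperiment::colData(ffs)))
  st <- significanceTable(ffs2)
  sig <- significantNodes(st)
  expect_true(all(inject %in% sig$node))
  expect_true(all(st@table[st@table$node %in% inject, "sig_HQ"]))
  expect_true(all(st@table[st@table$node %in% inject, "sig_YQ"]))
  ## discriminative sets follow the pair columns
  expect_true(all(inject %in% selectDiscriminative(st, "HQ")))
  expect_length(selectDiscriminative(st, "HQ", alpha = 1), 62L)
  expect_true(all(selectDiscriminative(st, "HY") %in% st@table$node))
  ## alpha = 0 empties the filtered view
  st0 <- significanceTable(ffs2, alpha = 0)
  expect_equal(nrow(significantNodes(st0)), 0L)
})

test_that("null cohort flags about the binomial-expected row count", {
  set.seed(77)
  hits <- numeric(20)
  for (i in 1:20) {
    ffs <- gaussianFeatureSet(nPer = c(Q = 25, Y = 20, H = 15),
                              shift = 0, seed = 1000 + i)
    hits[i] <- nrow(significantNodes(significanceTable(ffs)))
  }
  expected <- 62 * (1 - 0.95^3)
  expect_gt(mean(hits), expected - 4)
  expect_lt(mean(hits), expected + 4)
})

test_that("per-sex stratification equals running on the filtered cohort", {
  ffs <- gaussianFeatureSet(nPer = c(Q = 24, Y = 18, H = 14), shift = 1)
  male <- significanceTable(ffs, "male")
  sub <- ffs[, SummarizedExperiment::colData(ffs)$sex == "male"]
  expect_equal(male@table, significanceTable(sub, "all")@table)
})

test_that("BH adjustment is available and more conservative", {
  ffs <- gaussianFeatureSet(nPer = c(Q = 20, Y = 16, H = 12), shift = 0.8)
  raw <- significanceTable(ffs)
  bh <- significanceTable(ffs, adjustP = "BH")
  expect_lte(nrow(significantNodes(bh)), nrow(significantNodes(raw)))
  expect_true(all(bh@table$p_HQ >= raw@table$p_HQ - 1e-12))
})

test_that("stats CSV mirrors the per-subband report layout", {
  ffs <- gaussianFeatureSet(nPer = c(Q = 12, Y = 10, H = 8), shift = 1)
  st <- significanceTable(ffs)
  f <- withr::local_tempfile(fileext = ".csv")
  writeStatsCSV(st, f)
  got <- read.csv(f)
  expect_identical(colnames(got),
                   c("node", "band_khz", "H_mean", "H_std", "Y_mean",
                     "Y_std", "Q_mean", "Q_std", "p_HY", "p_HQ", "p_YQ",
                     "flags"))
  expect_equal(nrow(got), 62L)
})
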