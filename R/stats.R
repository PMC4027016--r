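## Age-adjusted per-subband group comparisons.
##
## Model per node: dimension ~ group + age (ANCOVA-style linear model
## with treatment dummies).  Pairwise p-values come from contrasts of
## the fitted coefficients with the model's estimated covariance
## (two-sided t tests on the residual df).  Reported means/SDs are raw
## per-group summaries; only the p-values are age-adjusted.

.PAIRS <- c("HY", "HQ", "YQ")

#' Age-adjusted comparison of one subband across groups
#'
#' Fits `value ~ group + age` and reports the three pairwise group
#' contrasts together with raw per-group means and standard
#' deviations.
#'
#' @param values Numeric vector of box dimensions, one per subject.
#' @param groups Group labels (`"Q"`, `"Y"`, `"H"`).
#' @param ages Ages in years; set `adjustAge = FALSE` to drop the
#'   covariate (plain one-way comparison).
#' @param alpha Significance level for the flags.
#' @param adjustAge Include age as covariate (default `TRUE`).
#' @return One-row `data.frame` with per-group `*_mean`/`*_sd`,
#'   `p_HY`, `p_HQ`, `p_YQ`, and logical `sig_*` flags at `alpha`.
#' @export
compareNode <- function(values, groups, ages, alpha = 0.05,
                        adjustAge = TRUE) {
  groups <- as.character(groups)
  present <- intersect(.GROUPS, unique(groups))
  if (length(present) < 2L)
    stop("need at least 2 groups present")
  tab <- table(groups)
  if (any(tab[present] < 3L))
    stop("each group needs at least 3 subjects")
  if (adjustAge && !all(is.finite(ages)))
    stop("ages must be finite")
  g <- factor(groups, levels = present)
  fit <- if (adjustAge)
    lm(values ~ g + age, data = data.frame(values = values, g = g,
                                           age = ages))
  else
    lm(values ~ g, data = data.frame(values = values, g = g))
  if (any(is.na(coef(fit))))
    stop("singular design (collinear group/age coding)")
  cf <- coef(fit)
  V <- vcov(fit)
  df <- fit$df.residual

  pairP <- function(g1, g2) {
    if (!all(c(g1, g2) %in% present)) return(NA_real_)
    ## contrast c: mean(g2) - mean(g1) adjusted; dummy coding vs present[1]
    cvec <- numeric(length(cf))
    names(cvec) <- names(cf)
    term <- function(gg) paste0("g", gg)
    if (term(g1) %in% names(cvec)) cvec[term(g1)] <- -1
    if (term(g2) %in% names(cvec)) cvec[term(g2)] <- 1
    est <- sum(cvec * cf)
    se <- sqrt(drop(t(cvec) %*% V %*% cvec))
    2 * pt(abs(est / se), df, lower.tail = FALSE)
  }

  out <- list()
  for (gg in .GROUPS) {
    v <- values[groups == gg]
    out[[paste0(gg, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    out[[paste0(gg, "_sd")]] <- if (length(v) > 1L) sd(v) else NA_real_
  }
  out$p_HY <- pairP("H", "Y")
  out$p_HQ <- pairP("H", "Q")
  out$p_YQ <- pairP("Y", "Q")
  out <- as.data.frame(out)
  for (p in .PAIRS)
    out[[paste0("sig_", p)]] <- !is.na(out[[paste0("p_", p)]]) &
      out[[paste0("p_", p)]] < alpha
  out
}

#' Per-subband significance table of a feature set
#'
#' Applies [compareNode()] to every node of a [FractalFeatureSet]
#' (optionally restricted to one sex) and assembles the full table;
#' a marker string mirrors the usual presentation (`*` significant vs
#' H, `^` vs Y, `#` vs Q from the perspective of each group's own
#' pairings is condensed to the pair flags here).
#'
#' @param ffs A [FractalFeatureSet].
#' @param stratum `"all"` (default), `"male"`, or `"female"`.
#' @param alpha Significance level.
#' @param adjustAge Include the age covariate (default `TRUE`).
#' @param adjustP Optional multiple-testing correction across nodes
#'   applied per pair: `"none"` (default, raw p-values) or `"BH"`.
#' @return A [SubbandStats].
#' @export
significanceTable <- function(ffs, stratum = c("all", "male", "female"),
                              alpha = 0.05, adjustAge = TRUE,
                              adjustP = c("none", "BH")) {
  stratum <- match.arg(stratum)
  adjustP <- match.arg(adjustP)
  cd <- SummarizedExperiment::colData(ffs)
  keep <- if (stratum == "all") rep(TRUE, ncol(ffs)) else cd$sex == stratum
  if (!any(keep)) stop("empty stratum: ", stratum)
  mat <- SummarizedExperiment::assay(ffs, "dimension")[, keep, drop = FALSE]
  groups <- cd$group[keep]
  ages <- cd$age[keep]
  rd <- as.data.frame(SummarizedExperiment::rowData(ffs))
  rows <- lapply(seq_len(nrow(mat)), function(i)
    compareNode(mat[i, ], groups, ages, alpha = alpha,
                adjustAge = adjustAge))
  tab <- cbind(
    data.frame(node = rownames(mat), level = rd$level, index = rd$index,
               band_khz = sprintf("%g-%g", rd$low_khz, rd$high_khz)),
    do.call(rbind, rows))
  if (adjustP == "BH") {
    for (p in .PAIRS) {
      tab[[paste0("p_", p)]] <- stats::p.adjust(tab[[paste0("p_", p)]],
                                                method = "BH")
      tab[[paste0("sig_", p)]] <- tab[[paste0("p_", p)]] < alpha
    }
  }
  SubbandStats(table = tab, stratum = stratum, alpha = alpha)
}

#' Nodes with at least one significant pairwise difference
#'
#' The filtered view of a [SubbandStats]: rows where any pairwise
#' age-adjusted p-value is below `alpha`.
#'
#' @param stats A [SubbandStats].
#' @return `data.frame` subset of the full table.
#' @export
significantNodes <- function(stats) {
  tab <- stats@table
  tab[tab$sig_HY | tab$sig_HQ | tab$sig_YQ, , drop = FALSE]
}

#' Discriminative node set for one group pair
#'
#' Returns the nodes whose pairwise p-value for the given pair is
#' below `alpha`, in canonical column order — the per-binary-classifier
#' feature subset.
#'
#' @param stats A [SubbandStats].
#' @param pair `"HY"`, `"HQ"`, or `"YQ"`.
#' @param alpha Significance threshold (defaults to the table's
#'   `alpha`).
#' @return Character vector of node names (possibly empty).
#' @export
selectDiscriminative <- function(stats, pair = c("HY", "HQ", "YQ"),
                                 alpha = NULL) {
  pair <- match.arg(pair)
  if (is.null(alpha)) alpha <- stats@alpha
  tab <- stats@table
  p <- tab[[paste0("p_", pair)]]
  tab$node[!is.na(p) & p < alpha]
}

#' Write a significance table as CSV
#'
#' Columns mirror the usual per-subband report:
#' `node,band_khz,H_mean,H_std,Y_mean,Y_std,Q_mean,Q_std,p_HY,p_HQ,p_YQ,flags`
#' where `flags` concatenates the significant pairs.
#'
#' @param stats A [SubbandStats].
#' @param path Output CSV path.
#' @param filtered If `TRUE`, write only [significantNodes()].
#' @return `path`, invisibly.
#' @export
writeStatsCSV <- function(stats, path, filtered = FALSE) {
  tab <- if (filtered) significantNodes(stats) else stats@table
  out <- data.frame(
    node = tab$node, band_khz = tab$band_khz,
    H_mean = tab$H_mean, H_std = tab$H_sd,
    Y_mean = tab$Y_mean, Y_std = tab$Y_sd,
    Q_mean = tab$Q_mean, Q_std = tab$Q_sd,
    p_HY = tab$p_HY, p_HQ = tab$p_HQ, p_YQ = tab$p_YQ,
    flags = apply(tab[, paste0("sig_", .PAIRS), drop = FALSE], 1,
                  function(f) paste(.PAIRS[f], collapse = "+")))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
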