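#' Shared statistics layer
#'
#' The summary and test statistics used across the comparison stages:
#' coefficient of variation, Cohen's d, paired t-test, IQR, Kruskal-Wallis,
#' one-way ANOVA with Tukey HSD, OLS regression, agglomerative clustering
#' and Bonferroni adjustment. Classical tests delegate to the standard
#' stats-package implementations; the simple effect-size formulas are
#' implemented directly. All operations consume plain vectors/tables so the
#' layer is reusable on precomputed CSVs.
#'
#' @name comparative-stats
NULL

#' Coefficient of variation (percent)
#'
#' `sd(x)/mean(x) * 100` with the sample (n-1) standard deviation.
#'
#' @param values numeric vector, length >= 2, nonzero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  if (abs(m) < .Machine$double.eps) stop("zero mean: CV undefined")
  100 * stats::sd(values) / m
}

#' CV from printed summary moments
#'
#' Evaluates `sigma/mu * 100` directly from a reported mean and standard
#' deviation (useful when only summary statistics are available).
#'
#' @param mu mean; `sigma` standard deviation.
#' @param sigma standard deviation.
#' @return CV in percent.
#' @export
cv_from_moments <- function(mu, sigma) {
  if (abs(mu) < .Machine$double.eps) stop("zero mean: CV undefined")
  100 * sigma / mu
}

#' Cohen's d from group moments
#'
#' `|mu1 - mu2| / sqrt((sd1^2 + sd2^2)/2)` (pooled-by-average form).
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @return effect size d (>= 0).
#' @export
cohens_d <- function(mean1, sd1, mean2, sd2) {
  if (sd1 < 0 || sd2 < 0) stop("standard deviations must be >= 0")
  if (sd1 == 0 && sd2 == 0) stop("both standard deviations zero: d undefined")
  abs(mean1 - mean2) / sqrt((sd1^2 + sd2^2) / 2)
}

#' Paired t-test
#'
#' @param values_a,values_b equal-length numeric vectors (n >= 3).
#' @param alpha significance level.
#' @return list with `t`, `p`, `significant`, `mean_difference`.
#' @export
paired_t <- function(values_a, values_b, alpha = 0.05) {
  if (length(values_a) != length(values_b)) stop("unequal lengths")
  if (length(values_a) < 3) stop("need at least 3 pairs")
  d <- values_a - values_b
  if (stats::sd(d) < 1e-10 * max(1, abs(mean(d)), abs(mean(values_a)))) {
    if (all(abs(d) < 1e-12)) return(list(t = 0, p = 1, significant = FALSE,
                                         mean_difference = 0))
    stop("zero-variance differences: t undefined")
  }
  tt <- stats::t.test(values_a, values_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha,
       mean_difference = unname(tt$estimate))
}

#' Kruskal-Wallis rank test
#'
#' Midranks with tie correction, chi-square p-value (the standard
#' implementation). Degenerate all-identical input returns H = 0, p = 1.
#'
#' @param groups list of numeric vectors (>= 2 groups, each nonempty).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) == 0)) stop("empty group")
  pooled <- unlist(groups)
  if (length(unique(pooled)) == 1) return(list(H = 0, p = 1))
  g <- factor(rep(seq_along(groups), lengths(groups)))
  kt <- stats::kruskal.test(pooled, g)
  list(H = unname(kt$statistic), p = kt$p.value)
}

#' Ordinary least-squares regression
#'
#' @param x,y numeric vectors, n >= 3, `var(x) > 0`.
#' @return list with `slope`, `intercept`, `r` (Pearson correlation).
#' @export
regression_slope <- function(x, y) {
  if (length(x) != length(y)) stop("unequal lengths")
  if (length(x) < 3) stop("need at least 3 points")
  if (stats::var(x) == 0) stop("zero variance in x")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y))
}

#' Agglomerative clustering of labeled points
#'
#' Average linkage on Euclidean distances between standardized (z-scored)
#' coordinates; used to group receptors by pocket (effective radius,
#' sphericity) characteristics.
#'
#' @param points data.frame or matrix with rownames as labels and numeric
#'   columns (e.g. `r_eff`, `sphericity`).
#' @param standardize z-score the columns first (default TRUE).
#' @return an `hclust` object (merge order, heights, labels).
#' @export
hierarchical_cluster <- function(points, standardize = TRUE) {
  m <- as.matrix(points)
  if (nrow(m) < 2) stop("need at least 2 labeled points")
  if (is.null(rownames(m))) stop("points must carry labels (rownames)")
  if (anyDuplicated(rownames(m))) stop("duplicate labels")
  if (standardize) {
    sds <- apply(m, 2, stats::sd)
    sds[sds == 0] <- 1
    m <- scale(m, scale = sds)
  }
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' @param groups named list of numeric vectors (>= 2 groups of n >= 2).
#' @param alpha significance level for the adjusted pairwise comparisons.
#' @return list with `F`, `p`, and `tukey` (data.frame of pairwise adjusted
#'   comparisons: `comparison`, `diff`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(lengths(groups) < 2)) stop("each group needs n >= 2")
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups),
                   group = factor(rep(names(groups), lengths(groups))))
  if (stats::var(df$value) == 0)
    return(list(F = 0, p = 1,
                tukey = data.frame(comparison = character(0), diff = numeric(0),
                                   p_adj = numeric(0), significant = logical(0))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          p_adj = tk[, "p adj"],
                          significant = tk[, "p adj"] < alpha,
                          row.names = NULL))
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for m comparisons.
#'
#' @param p_values numeric vector in [0, 1].
#' @return adjusted p-values.
#' @export
bonferroni_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Quartile summary (Type 7 linear-interpolation quantiles)
#'
#' @param values numeric vector.
#' @return list with `q1`, `q3`, `iqr`.
#' @export
iqr_stats <- function(values) {
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}
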