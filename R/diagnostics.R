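# Model-checking and group-comparison tests used around the canopy
# regressions: heteroscedasticity (Breusch-Pagan), spatial autocorrelation
# (Moran's I on inverse-distance weights), and the species comparisons
# (Wilcoxon rank sum, Levene).

#' Breusch-Pagan heteroscedasticity test
#'
#' Regresses the squared OLS residuals of `formula` on the same covariates
#' and tests whether they explain any variance. The default studentized
#' (Koenker) form has statistic `n * R2` of the auxiliary regression,
#' referred to chi-squared with as many df as covariates; the classical
#' form assumes Gaussian errors. The test operates on an ordinary linear
#' fit of the supplied formula (the conventional companion check for
#' regressions on scaled canopy data).
#'
#' @param formula model formula for the mean (an OLS fit).
#' @param data data.frame holding the variables.
#' @param studentized use the studentized (Koenker) statistic (default
#'   `TRUE`); `FALSE` gives the classical Breusch-Pagan form.
#' @return an `"htest"` object.
#' @export
breusch_pagan <- function(formula, data, studentized = TRUE) {
  lmtest::bptest(formula, data = data, studentize = studentized)
}

#' Inverse-distance spatial weights
#'
#' Pairwise weights `1 / d_ij` from Euclidean distances between zone
#' centroids, zero on the diagonal and not row-standardized.
#'
#' @param coords data.frame with columns `zone_id`, `x`, `y` (any consistent
#'   planar projection), or a two-column coordinate matrix.
#' @return symmetric weight matrix with zone ids as dimnames when supplied.
#' @export
inverse_distance_weights <- function(coords) {
  if (is.data.frame(coords)) {
    ids <- if ("zone_id" %in% names(coords)) coords$zone_id else NULL
    xy <- as.matrix(coords[, c("x", "y")])
  } else {
    ids <- rownames(coords)
    xy <- as.matrix(coords)
  }
  d <- as.matrix(stats::dist(xy))
  if (any(d[upper.tri(d)] == 0))
    stop("duplicate coordinates give infinite inverse-distance weights")
  w <- 1 / d
  diag(w) <- 0
  dimnames(w) <- list(ids, ids)
  w
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2` with `z` the centered
#' values and `S0` the sum of weights. The null expectation is
#' `-1 / (n - 1)`; the p-value is a two-sided normal test using the analytic
#' randomization variance (which involves the sample kurtosis of `z`).
#' Weights are used exactly as supplied -- no row standardization.
#'
#' @param values numeric vector, one value per zone (e.g. scaled canopy area
#'   averaged across years).
#' @param weights symmetric nonnegative weight matrix with zero diagonal,
#'   e.g. from [inverse_distance_weights()].
#' @return an `"htest"` with the observed I, its null expectation and s.d.,
#'   and the p-value (`NA` with a warning when `n < 4`, where the
#'   randomization variance is undefined).
#' @export
morans_i <- function(values, weights) {
  n <- length(values)
  if (n < 3L) stop("Moran's I needs at least 3 zones")
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == n, ncol(weights) == n)
  if (any(weights < 0)) stop("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop("weight matrix must have a zero diagonal")
  if (max(abs(weights - t(weights))) > 1e-8 * max(abs(weights)))
    stop("weight matrix must be symmetric")
  z <- values - mean(values)
  v <- sum(z^2)
  if (v == 0) stop("Moran's I undefined for constant values")
  s0 <- sum(weights)
  I <- (n / s0) * sum(weights * outer(z, z)) / v
  ei <- -1 / (n - 1)
  if (n >= 4L) {
    s1 <- 0.5 * sum((weights + t(weights))^2)
    s2 <- sum((rowSums(weights) + colSums(weights))^2)
    k <- n * sum(z^4) / v^2
    vi <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
             k * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
      ((n - 1) * (n - 2) * (n - 3) * s0^2) - ei^2
    sdi <- sqrt(vi)
    p <- 2 * pnorm(-abs((I - ei) / sdi))
  } else {
    warning("randomization variance undefined for n < 4; p-value is NA")
    sdi <- NA_real_; p <- NA_real_
  }
  structure(list(
    statistic = c(I = I), parameter = c(expectation = ei, sd = sdi),
    p.value = p, estimate = c(`Moran I` = I),
    method = "Moran's I (randomization variance, two-sided normal test)",
    data.name = deparse(substitute(values))
  ), class = "htest")
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test reporting the Mann-Whitney pairs statistic W
#' (the number of (a, b) pairs with a > b, ties counting one half). The
#' p-value is exact by enumeration when the smaller group has at most 10
#' observations and there are no ties, otherwise a normal approximation
#' with tie and continuity corrections is used.
#'
#' @param group_a,group_b numeric samples.
#' @return an `"htest"` object.
#' @export
wilcoxon_rank_sum <- function(group_a, group_b) {
  stopifnot(length(group_a) > 0, length(group_b) > 0)
  exact <- min(length(group_a), length(group_b)) <= 10 &&
    !anyDuplicated(c(group_a, group_b))
  suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                      correct = TRUE))
}

#' Levene test for homogeneity of variances
#'
#' One-way ANOVA on the absolute deviations of each observation from its
#' group center. The default median centering (Brown-Forsythe form) is
#' robust to non-normality; `center = "mean"` gives the classical Levene
#' statistic.
#'
#' @param values numeric observations, or a list of group vectors (then
#'   `groups` is ignored).
#' @param groups group labels aligned with `values`.
#' @param center `"median"` (default) or `"mean"`.
#' @return an `"htest"` with the F statistic, (df1, df2) and p-value.
#' @export
levene_test <- function(values, groups = NULL, center = c("median", "mean")) {
  center <- match.arg(center)
  if (is.list(values) && !is.data.frame(values)) {
    groups <- rep(seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  g <- factor(groups)
  if (nlevels(g) < 2L) stop("Levene test needs at least 2 groups")
  if (any(table(g) < 2L)) stop("every group needs at least 2 observations")
  cfun <- if (center == "median") median else mean
  centers <- tapply(values, g, cfun)
  dev <- abs(values - centers[as.integer(g)])
  a <- anova(lm(dev ~ g))
  structure(list(
    statistic = c(F = a$`F value`[1L]),
    parameter = c(df1 = a$Df[1L], df2 = a$Df[2L]),
    p.value = a$`Pr(>F)`[1L],
    method = paste0("Levene test (", center, "-centered)"),
    data.name = deparse(substitute(values))
  ), class = "htest")
}
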