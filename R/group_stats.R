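#' Two-sample t test with Cohen's d (pooled variance)
#'
#' Classic pooled-variance two-sample t test with `nA + nB - 2` degrees of
#' freedom and the standardized mean difference (Cohen's d, mean difference
#' over pooled SD).
#'
#' @param x,y Numeric vectors (each at least 2 values).
#' @return A list with `t`, `dof`, `p` (two-sided), `cohens_d`,
#'   `mean_diff`.
#' @export
two_sample_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  two_sample_t_summary(mean(x), stats::sd(x), length(x),
                       mean(y), stats::sd(y), length(y))
}

#' Two-sample t test from printed summary statistics
#'
#' Summary-statistic entry point: computes the pooled-variance t test and
#' Cohen's d directly from group means, SDs, and sizes, so reported group
#' statistics can be checked without raw data.
#'
#' @param mean1,sd1,n1 First group's mean, SD, and size.
#' @param mean2,sd2,n2 Second group's mean, SD, and size.
#' @return A list with `t`, `dof`, `p` (two-sided), `cohens_d`,
#'   `mean_diff`.
#' @examples
#' # harm-avoidance gender difference from printed cohort statistics
#' two_sample_t_summary(7.44, 4.40, 48, 5.07, 4.12, 30)$t
#' @export
two_sample_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  dof <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / dof
  if (sp2 <= 0) {
    stop("pooled variance is zero; effect size undefined", call. = FALSE)
  }
  sp <- sqrt(sp2)
  diff <- mean1 - mean2
  t <- diff / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, dof = dof,
       p = 2 * stats::pt(abs(t), df = dof, lower.tail = FALSE),
       cohens_d = diff / sp, mean_diff = diff)
}

#' Pearson or Spearman correlation with significance
#'
#' Pearson correlation tested with the t transform (`n - 2` df, two-sided);
#' Spearman computed as the Pearson correlation of average ranks (the same
#' t-transform p-value is reported, adequate at the cohort sizes used
#' here). Also reports `r_squared`, the fraction of variance accounted for.
#'
#' @param x,y Numeric vectors (n >= 4, finite).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list with `r`, `p`, `n`, `t`, `r_squared`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  out <- pearson_test(x, y)
  out$r_squared <- out$r^2
  out
}

#' Second-level trait regression on a contrast value
#'
#' Regresses a per-subject first-level contrast value on the three trait
#' scores (NS, HA, RD) with age and gender as covariates. Gender enters as
#' two indicator columns (male, female) with no separate intercept — the
#' indicators span the intercept, so trait coefficients are identical to
#' the single-indicator-plus-intercept parameterization while gender means
#' are read off directly.
#'
#' @param table A cohort data.frame with columns `NS`, `HA`, `RD`, `age`,
#'   `gender` (`"M"`/`"F"`), and the dependent contrast column.
#' @param dependent Name of the dependent contrast column (default
#'   `"contrast"`).
#' @return An object of class `"trait_regression"`: a coefficient
#'   data.frame (`estimate`, `se`, `t`, `p` per predictor) with attributes
#'   `r_squared`, `n`, `dependent`.
#' @export
trait_regression <- function(table, dependent = "contrast") {
  need <- c("NS", "HA", "RD", "age", "gender", dependent)
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  cc <- stats::complete.cases(table[, need])
  tab <- table[cc, ]
  y <- tab[[dependent]]
  X <- cbind(NS = tab$NS, HA = tab$HA, RD = tab$RD, age = tab$age,
             male = as.numeric(tab$gender == "M"),
             female = as.numeric(tab$gender == "F"))
  n <- nrow(X)
  if (n <= ncol(X)) stop("more predictors than subjects", call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    stop("collinear predictors beyond the designed gender pair",
         call. = FALSE)
  }
  beta <- qr.coef(qrX, y)
  res <- qr.resid(qrX, y)
  dof <- n - ncol(X)
  sigma2 <- sum(res^2) / dof
  covb <- sigma2 * chol2inv(qr.R(qrX))[order(qrX$pivot), order(qrX$pivot)]
  se <- sqrt(diag(covb))
  tval <- beta / se
  p <- 2 * stats::pt(abs(tval), df = dof, lower.tail = FALSE)
  # R^2 about the mean (the gender indicators span the intercept)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  out <- data.frame(predictor = colnames(X), estimate = beta, se = se,
                    t = tval, p = p, row.names = NULL)
  attr(out, "r_squared") <- r2
  attr(out, "n") <- n
  attr(out, "dependent") <- dependent
  class(out) <- c("trait_regression", "data.frame")
  out
}

#' @export
print.trait_regression <- function(x, ...) {
  cat(sprintf("Second-level regression of '%s' (n = %d, R^2 = %.3f)\n",
              attr(x, "dependent"), attr(x, "n"), attr(x, "r_squared")))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Compare two regression slopes (pooled-variance t test)
#'
#' Tests whether the simple-regression slope of `y` on `x` differs between
#' two independent groups, with the classical pooled-residual-variance
#' statistic: `t = (b1 - b2) / SE_diff`,
#' `SE_diff = sqrt(s2 * (1/Sxx1 + 1/Sxx2))`, where `s2` pools the residual
#' sums of squares over `n1 + n2 - 4` degrees of freedom.
#'
#' @param x1,y1 First group's predictor and response (n >= 3).
#' @param x2,y2 Second group's predictor and response (n >= 3).
#' @return A list with `t`, `dof`, `p` (two-sided), `slope1`, `slope2`.
#' @export
compare_slopes <- function(x1, y1, x2, y2) {
  ok1 <- is.finite(x1) & is.finite(y1)
  ok2 <- is.finite(x2) & is.finite(y2)
  x1 <- x1[ok1]; y1 <- y1[ok1]; x2 <- x2[ok2]; y2 <- y2[ok2]
  if (length(x1) < 3 || length(x2) < 3) {
    stop("each group needs at least 3 complete pairs", call. = FALSE)
  }
  sxx1 <- sum((x1 - mean(x1))^2)
  sxx2 <- sum((x2 - mean(x2))^2)
  if (sxx1 == 0 || sxx2 == 0) {
    stop("zero predictor variance in a group; slope undefined",
         call. = FALSE)
  }
  b1 <- sum((x1 - mean(x1)) * (y1 - mean(y1))) / sxx1
  b2 <- sum((x2 - mean(x2)) * (y2 - mean(y2))) / sxx2
  rss1 <- sum((y1 - mean(y1) - b1 * (x1 - mean(x1)))^2)
  rss2 <- sum((y2 - mean(y2) - b2 * (x2 - mean(x2)))^2)
  dof <- length(x1) + length(x2) - 4
  s2 <- (rss1 + rss2) / dof
  se <- sqrt(s2 * (1 / sxx1 + 1 / sxx2))
  t <- (b1 - b2) / se
  list(t = t, dof = dof,
       p = 2 * stats::pt(abs(t), df = dof, lower.tail = FALSE),
       slope1 = b1, slope2 = b2)
}

#' Bonferroni-adjust the trait p-values of second-level reports
#'
#' Convenience wrapper applying a Bonferroni correction across the trait
#' (NS, HA, RD) p-values of one or more [trait_regression()] reports, the
#' guard used when several traits (and regions) are tested jointly.
#'
#' @param reports A list of [trait_regression()] objects (or a single one).
#' @param alpha Family-wise error level (default 0.05).
#' @return A data.frame with one row per report x trait: `dependent`,
#'   `predictor`, `p`, `p_bonferroni`, `significant`.
#' @export
bonferroni_traits <- function(reports, alpha = 0.05) {
  if (inherits(reports, "trait_regression")) reports <- list(reports)
  rows <- do.call(rbind, lapply(reports, function(rep) {
    tr <- rep[rep$predictor %in% c("NS", "HA", "RD"), ]
    data.frame(dependent = attr(rep, "dependent"),
               predictor = tr$predictor, p = tr$p)
  }))
  m <- nrow(rows)
  rows$p_bonferroni <- pmin(rows$p * m, 1)
  rows$significant <- rows$p_bonferroni < alpha
  rows
}
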