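#' Pearson correlation with a two-sided t-test
#'
#' Sample Pearson r with the usual two-sided p-value from
#' \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors, n >= 3, finite, nonzero variance.
#' @return list: `r`, `p`, `n`, `df`.
#' @export
pearson <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  stop_if_not_finite(x, "x"); stop_if_not_finite(y, "y")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  list(r = r, p = p, n = n, df = df)
}

#' Covariate-corrected (partial) Pearson correlation
#'
#' Correlation between the residuals of x and y after ordinary least-squares
#' regression on the covariates (plus intercept); the p-value uses
#' n - 2 - c degrees of freedom for c covariates. With no covariates this is
#' identical to [pearson()].
#'
#' @param x,y numeric vectors.
#' @param covariates numeric matrix/data frame with one column per covariate,
#'   or `NULL`.
#' @return list: `r`, `p`, `n`, `df`, `n_covariates`.
#' @export
partial_pearson <- function(x, y, covariates = NULL) {
  if (is.null(covariates) || NCOL(covariates) == 0) {
    out <- pearson(x, y)
    out$n_covariates <- 0L
    return(out)
  }
  Z <- as.matrix(covariates)
  n <- length(x)
  c <- ncol(Z)
  stopifnot(length(y) == n, nrow(Z) == n)
  if (n < c + 3) stop("need at least covariates + 3 observations", call. = FALSE)
  rx <- stats::residuals(stats::lm(x ~ Z))
  ry <- stats::residuals(stats::lm(y ~ Z))
  if (stats::var(rx) < 1e-14 * max(stats::var(x), 1) ||
      stats::var(ry) < 1e-14 * max(stats::var(y), 1)) {
    stop("zero residual variance after covariate adjustment", call. = FALSE)
  }
  r <- stats::cor(rx, ry)
  df <- n - 2 - c
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt(df / (1 - r^2))
    2 * stats::pt(-abs(t), df)
  }
  list(r = r, p = p, n = n, df = df, n_covariates = c)
}

#' Paired comparison of two region measurements
#'
#' Two-sided paired t-test on the within-subject differences (default), or
#' the Wilcoxon signed-rank test for small non-normal samples. A zero-variance
#' difference vector is flagged degenerate: the mean difference is reported
#' with p = 1 when it is zero, p = 0 otherwise.
#'
#' @param a,b paired measurements (same subjects, same order), n >= 3.
#' @param method `"t"` or `"wilcoxon"`.
#' @return list: `mean_difference`, `p`, `n`, `method`, `degenerate`.
#' @export
paired_region_test <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- a - b
  if (stats::sd(d) <= 1e-10 * max(abs(d), 1e-300)) {
    return(list(mean_difference = mean(d),
                p = if (isTRUE(all.equal(mean(d), 0))) 1 else 0,
                n = n, method = method, degenerate = TRUE))
  }
  p <- if (method == "t") {
    stats::t.test(a, b, paired = TRUE)$p.value
  } else {
    stats::wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value
  }
  list(mean_difference = mean(d), p = p, n = n, method = method,
       degenerate = FALSE)
}

#' Batch association screen over variable pairs
#'
#' One row per (pair, covariate set): Pearson or partial Pearson r, p and n.
#' No multiplicity correction is applied by default, mirroring exploratory
#' small-cohort practice; set `p_adjust = "BH"` for Benjamini-Hochberg
#' adjusted p-values in an extra clearly labelled column.
#'
#' @param records data frame of subject records.
#' @param pairs data frame with columns `x`, `y` naming record columns.
#' @param covariate_map optional named list: for entry `"x|y"`, a character
#'   vector of covariate column names to correct that pair for.
#' @param p_adjust `"none"` or `"BH"`.
#' @return data frame: x, y, covariates, r, p, n (plus `p_adj` when adjusted).
#' @export
association_screen <- function(records, pairs, covariate_map = list(),
                               p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  vars <- unique(c(pairs$x, pairs$y, unlist(covariate_map)))
  missing <- setdiff(vars, names(records))
  if (length(missing)) {
    stop("variables not in records: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    xv <- pairs$x[i]; yv <- pairs$y[i]
    cov_names <- covariate_map[[paste(xv, yv, sep = "|")]]
    res <- partial_pearson(records[[xv]], records[[yv]],
                           if (length(cov_names)) records[cov_names] else NULL)
    data.frame(x = xv, y = yv,
               covariates = paste(cov_names, collapse = "+"),
               r = res$r, p = res$p, n = res$n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (p_adjust == "BH") out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Fisher z confidence band for a sample correlation
#'
#' The 95% (or `level`) interval for the sample r around a population rho at
#' sample size n, via the z transform with standard error 1/sqrt(n - 3).
#'
#' @param rho population correlation.
#' @param n sample size.
#' @param level confidence level.
#' @return length-2 vector (lower, upper).
#' @export
fisher_z_band <- function(rho, n, level = 0.95) {
  z <- atanh(rho)
  q <- stats::qnorm(1 - (1 - level) / 2)
  tanh(z + c(-1, 1) * q / sqrt(n - 3))
}
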