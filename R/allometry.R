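#' Log10-transform selected traits of a species table
#'
#' Allometric analysis runs on log10-transformed species means. Nonpositive
#' values cannot be log-transformed; the error names the offending species and
#' trait.
#'
#' @param table Species-by-trait data frame (rownames = species).
#' @param traits Trait columns to transform.
#' @return Numeric matrix of log10 values (species x traits); `NA`s are kept
#'   and handled pairwise downstream.
#' @export
log10_prepare <- function(table, traits) {
  miss <- setdiff(traits, names(table))
  if (length(miss)) stop("schema error: trait column(s) absent: ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(table[traits])
  bad <- which(!is.na(m) & m <= 0, arr.ind = TRUE)
  if (nrow(bad)) {
    sp <- rownames(m)[bad[1L, 1L]] %||% as.character(bad[1L, 1L])
    stop("invalid-argument: nonpositive value for species '", sp,
         "', trait '", traits[bad[1L, 2L]], "' cannot be log10-transformed")
  }
  log10(m)
}

#' Standardized major axis (SMA) regression
#'
#' Fits the allometric line `Y = alpha + beta X` on log-log data by
#' standardized major axis: `beta = sign(cov(x, y)) * sd(y) / sd(x)`,
#' `alpha = mean(y) - beta * mean(x)`. The 95% confidence interval on the
#' slope is `beta * (sqrt(B + 1) +/- sqrt(B))` with
#' `B = F(0.95; 1, n-2) * (1 - r^2) / (n - 2)`. SMA is symmetric in the two
#' axes (swapping them inverts the slope), which is why it is the standard for
#' bivariate scaling relationships where neither variable is "the predictor".
#'
#' @param x,y Numeric vectors (log scale); pairwise-complete, `n >= 3`.
#' @param b0 Optional hypothesized slope; if supplied, the isometry/allometry
#'   test [sma_slope_test()] p-value is included.
#' @param conf Confidence level for the slope interval.
#' @return Object of class `sma_fit`: `n`, `slope`, `intercept`, `r_squared`,
#'   `ci_low`, `ci_high`, optional `b0`/`p_value`, `degenerate` flag.
#' @examples
#' fit <- sma_fit(log10(c(1, 2, 4, 8)), log10(c(2, 4, 8, 16)))
#' fit$slope
#' @export
sma_fit <- function(x, y, b0 = NULL, conf = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("invalid-argument: SMA needs n >= 3 complete pairs")
  if (var(x) == 0 || var(y) == 0)
    stop("degenerate-input: zero variance in x or y")
  r <- cor(x, y)
  sgn <- if (r == 0) 1 else sign(r)
  slope <- sgn * sd(y) / sd(x)
  intercept <- mean(y) - slope * mean(x)
  r2 <- r^2
  degenerate <- isTRUE(all.equal(r2, 1))
  B <- qf(conf, 1, n - 2) * (1 - r2) / (n - 2)
  ci <- sort(slope * (sqrt(B + 1) + c(-1, 1) * sqrt(B)))
  out <- list(n = n, slope = slope, intercept = intercept, r_squared = r2,
              ci_low = ci[1L], ci_high = ci[2L], conf = conf,
              degenerate = degenerate)
  if (!is.null(b0)) {
    out$b0 <- b0
    out$p_value <- sma_slope_test(x, y, b0)
  }
  structure(out, class = "sma_fit")
}

#' @export
print.sma_fit <- function(x, ...) {
  cat(sprintf("SMA fit (n = %d)\n", x$n))
  cat(sprintf("  slope     %.4g  [%.4g, %.4g] (%.0f%% CI)\n",
              x$slope, x$ci_low, x$ci_high, 100 * x$conf))
  cat(sprintf("  intercept %.4g\n  r^2       %.4g\n", x$intercept, x$r_squared))
  if (!is.null(x$b0))
    cat(sprintf("  H0 slope = %g: p = %.4g\n", x$b0, x$p_value))
  if (x$degenerate) cat("  note: perfectly collinear data (degenerate CI)\n")
  invisible(x)
}

#' Test an SMA slope against a hypothesized value
#'
#' The SMA analogue of a slope t-test: under `H0: beta = b0` the residual-axis
#' scores `y - b0 x` and fitted-axis scores `y + b0 x` are uncorrelated, so the
#' test computes their correlation `r` and refers
#' `t = r * sqrt((n - 2) / (1 - r^2))` to a t distribution with `n - 2` df
#' (two-sided). Testing `b0 = 1` (or `-1` for negative relationships) is the
#' isometry-vs-allometry test.
#'
#' @param x,y Numeric vectors (log scale).
#' @param b0 Hypothesized slope, nonzero.
#' @return Two-sided p-value. Perfectly collinear data lying exactly on slope
#'   `b0` return `p = 1` with a `degenerate` attribute.
#' @export
sma_slope_test <- function(x, y, b0 = 1) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("invalid-argument: need n >= 3")
  if (!is.finite(b0) || b0 == 0) stop("invalid-argument: b0 must be nonzero")
  u <- y - b0 * x
  v <- y + b0 * x
  if (sd(u) <= 1e-10 * sd(v) || sd(v) <= 1e-10 * sd(u)) {
    # data on the hypothesized (or anti-hypothesized) line up to rounding;
    # residuals are then numerical noise and carry no evidence against b0
    return(structure(1, degenerate = TRUE))
  }
  r <- cor(u, v)
  if (abs(r) >= 1) return(structure(0, degenerate = TRUE))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(tstat), df = n - 2)
}

#' Common-slope (slope heterogeneity) test across groups
#'
#' Finds the common SMA slope `b` minimizing the likelihood-ratio statistic
#' `LR(b) = -sum(n_i * log(1 - r_i(b)^2))`, where `r_i(b)` is group i's
#' correlation between residual (`y - b x`) and fitted-axis (`y + b x`)
#' scores. Heterogeneity of slopes is judged by referring `LR(b_common)` to a
#' chi-squared distribution with `k - 1` df. Minimization is one-dimensional
#' golden-section/Brent search on the sign-consistent bracket
#' `[min |b_i|/3, 3 max |b_i|]`.
#'
#' @param groups List of >= 2 groups, each a list with numeric `x` and `y`
#'   (each `n >= 3`). Groups must share the sign of their x-y correlation.
#' @return List with `b_common`, `lr`, `df`, `p_heterogeneity` and the
#'   per-group SMA `slopes`.
#' @export
common_slope_test <- function(groups) {
  if (length(groups) < 2L) stop("invalid-argument: need >= 2 groups")
  k <- length(groups)
  fits <- lapply(groups, function(g) sma_fit(g$x, g$y))
  slopes <- vapply(fits, `[[`, numeric(1), "slope")
  sgn <- sign(slopes)
  if (length(unique(sgn)) > 1L)
    stop("mixed correlation signs across groups; analyse positive and ",
         "negative relationships separately")
  sgn <- sgn[1L]
  ns <- vapply(groups, function(g) sum(is.finite(g$x) & is.finite(g$y)),
               numeric(1))
  lr <- function(b) {
    -sum(vapply(groups, function(g) {
      ok <- is.finite(g$x) & is.finite(g$y)
      u <- g$y[ok] - b * g$x[ok]
      v <- g$y[ok] + b * g$x[ok]
      if (sd(u) == 0 || sd(v) == 0) return(0)
      r2 <- cor(u, v)^2
      sum(ok) * log(max(1 - r2, .Machine$double.eps))
    }, numeric(1)))
  }
  lo <- min(abs(slopes)) / 3
  hi <- max(abs(slopes)) * 3
  opt <- optimize(function(b) lr(sgn * b), interval = c(lo, hi),
                  tol = .Machine$double.eps^0.5)
  b_common <- sgn * opt$minimum
  stat <- max(opt$objective, 0)
  list(b_common = b_common, lr = stat, df = k - 1,
       p_heterogeneity = pchisq(stat, df = k - 1, lower.tail = FALSE),
       slopes = slopes, n = ns)
}

#' Table of SMA fits for a list of trait pairs
#'
#' Convenience wrapper producing a results table shaped like a published
#' allometry table: one row per (Y, X) pair with `R2`, `slope`, the 95% CI and
#' the p-value of the test against the hypothesized slope (`+1`/`-1`).
#'
#' @param logm Matrix of log10 species means ([log10_prepare()]).
#' @param pairs Data frame with columns `y`, `x` and optionally `b0`
#'   (defaults: `-1` when the observed correlation is negative, else `+1`).
#' @return Data frame: `Y`, `X`, `n`, `R2`, `slope`, `ci_low`, `ci_high`,
#'   `b0`, `P`.
#' @export
sma_table <- function(logm, pairs) {
  stopifnot(all(c("y", "x") %in% names(pairs)))
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    yv <- logm[, pairs$y[i]]
    xv <- logm[, pairs$x[i]]
    ok <- is.finite(xv) & is.finite(yv)
    b0 <- if ("b0" %in% names(pairs) && is.finite(pairs$b0[i])) pairs$b0[i] else
      sign(cor(xv[ok], yv[ok]))
    fit <- sma_fit(xv, yv, b0 = b0)
    data.frame(Y = pairs$y[i], X = pairs$x[i], n = fit$n,
               R2 = fit$r_squared, slope = fit$slope,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               b0 = b0, P = as.numeric(fit$p_value))
  })
  do.call(rbind, rows)
}

#' Ordinary least squares diagnostic fit
#'
#' Labeled OLS companion to [sma_fit()] for diagnostics only; OLS slopes are
#' attenuated by x-error and are not used in the scaling analyses.
#'
#' @param x,y Numeric vectors.
#' @return List with `slope`, `intercept`, `r_squared`.
#' @export
ols_fit <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  fit <- lm(y[ok] ~ x[ok])
  list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
       r_squared = cor(x[ok], y[ok])^2)
}
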