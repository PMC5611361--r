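test_that("log10_prepare transforms and names domain violations", {
  tab <- data.frame(A = c(100, 1), B = c(10, 1000))
  rownames(tab) <- c("spX", "spY")
  m <- log10_prepare(tab, c("A", "B"))
  expect_equal(m, matrix(c(2, 0, 1, 3), 2, dimnames = list(c("spX", "spY"),
                                                           c("A", "B"))))
  tab$A[2] <- 0
  expect_error(log10_prepare(tab, c("A", "B")), "spY")
  expect_error(log10_prepare(tab, c("A", "B")), "'A'")
})

test_that("SMA fit: exact line, longhand moments oracle, symmetry", {
  fit <- sma_fit(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, 1)
  expect_true(fit$degenerate)

  x <- c(1, 2, 3, 4); y <- c(1.2, 1.9, 3.4, 3.9)
  # independent moments oracle
  slope_o <- sign(cov(x, y)) * sd(y) / sd(x)
  fit2 <- sma_fit(x, y)
  expect_equal(fit2$slope, slope_o, tolerance = 1e-12)
  expect_equal(round(fit2$slope, 3), 0.978)
  expect_equal(round(fit2$intercept, 3), 0.156)
  expect_equal(round(fit2$r_squared, 3), 0.964)
  B <- qf(0.95, 1, 2) * (1 - cor(x, y)^2) / 2
  expect_equal(fit2$ci_low, slope_o * (sqrt(B + 1) - sqrt(B)))
  expect_equal(fit2$ci_high, slope_o * (sqrt(B + 1) + sqrt(B)))

  # axis swap inverts the slope; affine rescaling is equivariant
  fit_sw <- sma_fit(y, x)
  expect_equal(fit_sw$slope, 1 / fit2$slope, tolerance = 1e-12)
  fit_sc <- sma_fit(2 * x + 3, 5 * y - 1)
  expect_equal(fit_sc$slope, fit2$slope * 5 / 2, tolerance = 1e-12)

  # negative relationship keeps CI ordered around a negative slope
  fit_n <- sma_fit(x, -y)
  expect_equal(fit_n$slope, -fit2$slope)
  expect_true(fit_n$ci_low <= fit_n$slope && fit_n$slope <= fit_n$ci_high)

  expect_error(sma_fit(c(1, 2), c(1, 2)), "n >= 3")
  expect_error(sma_fit(c(1, 1, 1), c(1, 2, 3)), "degenerate-input")
})

test_that("slope test: orthogonality at the estimate, permutation oracle", {
  x <- c(1, 2, 3, 4); y <- c(1.2, 1.9, 3.4, 3.9)
  b_hat <- sma_fit(x, y)$slope
  # residual and fitted-axis scores are exactly uncorrelated at the estimate
  expect_equal(cor(y - b_hat * x, y + b_hat * x), 0, tolerance = 1e-12)
  expect_equal(sma_slope_test(x, y, b_hat), 1, tolerance = 1e-6)
  # data exactly on the hypothesized line
  expect_equal(as.numeric(sma_slope_test(x, x, 1)), 1)

  # permutation oracle for the p-value at b0 = 1: with only 4 points the
  # permutation null is coarse (24 atoms), so agreement is loose there and
  # tight on a larger sample where the t reference applies smoothly
  p_t <- sma_slope_test(x, y, 1)
  set.seed(7)
  u <- y - x; v <- y + x
  r_obs <- abs(cor(u, v))
  r_perm <- replicate(20000, abs(cor(sample(u), v)))
  expect_equal(p_t, mean(r_perm >= r_obs - 1e-12), tolerance = 0.05)
  x2 <- c(0.4, 0.9, 1.3, 1.8, 2.2, 2.7, 3.1, 3.4, 3.9, 4.3, 4.8, 5.1)
  y2 <- c(0.7, 0.8, 1.6, 1.7, 2.5, 2.4, 3.5, 3.2, 4.3, 4.1, 5.2, 4.9)
  p_t2 <- sma_slope_test(x2, y2, 1)
  u2 <- y2 - x2; v2 <- y2 + x2
  r_obs2 <- abs(cor(u2, v2))
  r_perm2 <- replicate(20000, abs(cor(sample(u2), v2)))
  expect_equal(p_t2, mean(r_perm2 >= r_obs2 - 1e-12), tolerance = 0.02)
  expect_error(sma_slope_test(x, y, 0), "b0")
})

test_that("isometry test type-I error is calibrated (Monte Carlo)", {
  set.seed(202)
  n <- 28
  rej <- replicate(2000, {
    x <- rnorm(n)
    y <- sqrt(0.8) * x + rnorm(n, 0, sqrt(0.2)) # true SMA slope 1
    sma_slope_test(x, y, 1) < 0.05
  })
  expect_gte(mean(rej), 0.035)
  expect_lte(mean(rej), 0.065)
})

test_that("common slope: degenerate homogeneity, heterogeneity, calibration", {
  x <- c(1, 2, 3, 4, 5); y <- c(1.1, 2.3, 2.9, 4.2, 4.8)
  g <- list(x = x, y = y)
  res <- common_slope_test(list(g, g, g))
  expect_equal(res$b_common, sma_fit(x, y)$slope, tolerance = 1e-6)
  expect_lt(res$lr, 1e-8)
  expect_gt(res$p_heterogeneity, 0.999)

  # two noise-free lines with slopes 1 and 2: maximal heterogeneity
  res2 <- common_slope_test(list(list(x = x, y = x),
                                 list(x = x, y = 2 * x)))
  expect_lt(res2$p_heterogeneity, 0.001)

  expect_error(common_slope_test(list(list(x = x, y = y),
                                      list(x = x, y = -y))),
               "sign")

  # Monte-Carlo calibration: equal true slopes, alpha = 0.05
  set.seed(33)
  rej <- replicate(500, {
    mk <- function(n) {
      x <- rnorm(n)
      list(x = x, y = sqrt(0.8) * x + rnorm(n, 0, sqrt(0.2)))
    }
    common_slope_test(list(mk(25), mk(25)))$p_heterogeneity < 0.05
  })
  expect_gte(mean(rej), 0.03)
  expect_lte(mean(rej), 0.07)
})

test_that("sma_table assembles published-style rows with sign-matched b0", {
  set.seed(5)
  x <- rnorm(20); tab <- data.frame(A = 10^x, B = 10^(x + rnorm(20, 0, 0.1)),
                                    C = 10^(-x + rnorm(20, 0, 0.1)))
  rownames(tab) <- paste0("sp", 1:20)
  logm <- log10_prepare(tab, c("A", "B", "C"))
  res <- sma_table(logm, data.frame(y = c("B", "C"), x = c("A", "A")))
  expect_equal(res$b0, c(1, -1))
  expect_true(all(res$ci_low <= res$slope & res$slope <= res$ci_high))
  expect_true(res$slope[2] < 0)
})
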