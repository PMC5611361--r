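test_that("pearson matrix matches a longhand moments oracle", {
  tab <- data.frame(A = c(1, 2, 4, 6, 9), B = c(2.1, 3.8, 8.5, 11.6, 18.4),
                    C = c(5, 4, 3.5, 2, 1))
  pm <- pearson_matrix(tab)
  # longhand covariance computation for one cell
  a <- tab$A - mean(tab$A); b <- tab$B - mean(tab$B)
  r_oracle <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  expect_equal(pm$r["A", "B"], r_oracle, tolerance = 1e-12)
  expect_equal(unname(diag(pm$r)), rep(1, 3))
  expect_equal(pm$r, t(pm$r))
  expect_equal(pm$r["A", "A"], 1)
  # trait vs its negation
  tab$D <- -tab$A
  expect_equal(pearson_matrix(tab)$r["A", "D"], -1)
  # p-value matches cor.test
  ct <- cor.test(tab$A, tab$B)
  expect_equal(pm$p["A", "B"], ct$p.value, tolerance = 1e-10)
  # < 3 complete pairs -> NA cell
  tab$E <- c(1, 2, NA, NA, NA)
  pm2 <- pearson_matrix(tab)
  expect_true(is.na(pm2$r["E", "B"]))
  expect_equal(pm2$n["E", "B"], 2)
})

test_that("single-group MFA equals PCA; percentages sum to 100", {
  set.seed(4)
  m <- matrix(rnorm(28 * 6), 28, dimnames = list(NULL, paste0("t", 1:6)))
  res <- mfa(m, list(all = colnames(m)))
  pca <- prcomp(m, center = TRUE, scale. = TRUE)
  pct_pca <- 100 * pca$sdev^2 / sum(pca$sdev^2)
  expect_equal(res$variance_percent, pct_pca, tolerance = 1e-8)
  expect_equal(sum(res$variance_percent), 100, tolerance = 1e-8)
  # loadings columns orthogonal
  ltl <- crossprod(res$loadings)
  expect_equal(ltl, diag(nrow(ltl)), tolerance = 1e-8, ignore_attr = TRUE)
  # total inertia conservation: sum of axis variances = score inertia
  expect_equal(sum(res$eigenvalues),
               sum(res$scores^2) / (nrow(m) - 1), tolerance = 1e-8)
})

test_that("duplicating a group rescales all axes uniformly", {
  set.seed(9)
  m <- matrix(rnorm(25 * 8), 25)
  colnames(m) <- paste0("t", 1:8)
  m2 <- cbind(m, m)
  colnames(m2) <- c(paste0("t", 1:8), paste0("u", 1:8))
  r1 <- mfa(m, list(g = paste0("t", 1:8)))
  r2 <- mfa(m2, list(g1 = paste0("t", 1:8), g2 = paste0("u", 1:8)))
  expect_equal(r2$variance_percent[1:8], r1$variance_percent,
               tolerance = 1e-8)
  expect_error(mfa(cbind(m, const = 1),
                   list(g = c("t1", "const"))), "constant")
})

test_that("two-group MFA balances: neither group dominates axis 1", {
  ds <- simulate_dataset(simulation_config(seed = 3))
  logm <- log10_prepare(ds$species_means, names(ds$species_means))
  res <- mfa(logm, default_trait_groups())
  expect_equal(sum(res$variance_percent), 100, tolerance = 1e-8)
  expect_gt(res$variance_percent[1], res$variance_percent[2])
  # per-group contribution to axis 1 is bounded (block weighting at work)
  grp <- rep(names(default_trait_groups()),
             lengths(default_trait_groups()))
  con <- tapply(res$loadings[, 1]^2, grp, sum)
  expect_true(all(con > 0.1 & con < 0.9))
})

test_that("nested variance components match the EMS oracle on balanced data", {
  # 2 species x 2 individuals x 2 twigs with known effect sizes
  sp_eff <- c(spA = -3, spB = 3)
  ind_eff <- c(-1, 1)
  tw_eff <- c(-0.5, 0.5)
  df <- expand.grid(twig = 1:2, individual = 1:2, species = c("spA", "spB"))
  df$y <- sp_eff[df$species] + ind_eff[df$individual] + tw_eff[df$twig]
  vc <- nested_varcomp(df, "y")
  # EMS oracle: compute the three mean squares longhand
  gmean <- mean(df$y)
  spm <- tapply(df$y, df$species, mean)
  indm <- tapply(df$y, paste(df$species, df$individual), mean)
  ms_sp <- sum(4 * (spm - gmean)^2) / 1
  ms_ind <- sum(2 * (indm - rep(spm, each = 2))^2) / 2
  ms_tw <- sum((df$y - indm[paste(df$species, df$individual)])^2) / 4
  expect_equal(unname(vc$mean_squares),
               unname(c(ms_sp, ms_ind, ms_tw)), tolerance = 1e-12)
  expect_equal(unname(vc$sigma2["twig"]), ms_tw)
  expect_equal(unname(vc$sigma2["individual"]), max((ms_ind - ms_tw) / 2, 0))
  expect_equal(unname(vc$sigma2["species"]), max((ms_sp - ms_ind) / 4, 0))
  expect_equal(sum(vc$percent), 100)

  # individuals identical within species, species differing
  df2 <- df; df2$y <- sp_eff[df2$species]
  vc2 <- nested_varcomp(df2, "y")
  expect_equal(unname(vc2$percent["species"]), 100)

  # all values equal -> zero components, flagged
  df3 <- df; df3$y <- 1
  vc3 <- nested_varcomp(df3, "y")
  expect_true(vc3$all_equal)
  expect_equal(unname(vc3$percent), c(0, 0, 0))

  # single species rejected
  expect_error(nested_varcomp(df[df$species == "spA", ], "y"),
               "invalid-argument")
})

test_that("varcomp agrees with lme4 on an unbalanced design", {
  set.seed(77)
  rows <- list()
  for (s in 1:10) {
    sp_eff <- rnorm(1, 0, 2)
    for (i in 1:3) {
      ind_eff <- rnorm(1, 0, 0.7)
      nt <- sample(2:5, 1)
      rows[[length(rows) + 1]] <- data.frame(
        species = paste0("sp", s), individual = i, twig = seq_len(nt),
        y = sp_eff + ind_eff + rnorm(nt, 0, 0.4))
    }
  }
  df <- do.call(rbind, rows)
  vc <- nested_varcomp(df, "y")
  fit <- lme4::lmer(y ~ 1 + (1 | species / individual), data = df,
                    REML = TRUE)
  vv <- as.data.frame(lme4::VarCorr(fit))
  ref <- setNames(vv$vcov, vv$grp)
  tot_ref <- sum(ref)
  pct_ref <- 100 * c(ref[["species"]], ref[["individual:species"]],
                     ref[["Residual"]]) / tot_ref
  expect_equal(unname(vc$percent), pct_ref, tolerance = 8) # percentage points
})
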