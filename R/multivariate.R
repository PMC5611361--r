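#' Pairwise Pearson correlation matrix with p-values
#'
#' Species-level trait correlations with pairwise-complete observations.
#' Cells with fewer than 3 complete pairs are flagged `NA`. p-values use the
#' usual `t` with `n - 2` df. For contrast-level correlations use
#' [pic_correlation()] via `pearson_matrix(contrast_list)`.
#'
#' @param table Species-by-trait data frame or matrix (typically log10
#'   means), or a named list of `contrast_set`s, in which case through-origin
#'   contrast correlations are computed instead.
#' @return List of matrices `r`, `p`, `n`.
#' @export
pearson_matrix <- function(table) {
  if (is.list(table) && !is.data.frame(table) &&
      all(vapply(table, inherits, logical(1), "contrast_set"))) {
    traits <- names(table)
    p <- r <- matrix(NA_real_, length(traits), length(traits),
                     dimnames = list(traits, traits))
    nm <- matrix(NA_real_, length(traits), length(traits),
                 dimnames = list(traits, traits))
    for (i in seq_along(traits)) for (j in seq_len(i)) {
      pc <- pic_correlation(table[[i]], table[[j]])
      r[i, j] <- r[j, i] <- pc$r
      p[i, j] <- p[j, i] <- pc$p_value
      nm[i, j] <- nm[j, i] <- pc$df + 1L
    }
    diag(r) <- 1
    return(list(r = r, p = p, n = nm))
  }
  m <- as.matrix(table)
  traits <- colnames(m)
  k <- length(traits)
  r <- matrix(NA_real_, k, k, dimnames = list(traits, traits))
  p <- r
  nm <- r
  for (i in seq_len(k)) for (j in seq_len(i)) {
    ok <- is.finite(m[, i]) & is.finite(m[, j])
    n <- sum(ok)
    nm[i, j] <- nm[j, i] <- n
    if (n < 3L) next # flagged NA
    rij <- cor(m[ok, i], m[ok, j])
    r[i, j] <- r[j, i] <- rij
    p[i, j] <- p[j, i] <- if (abs(rij) >= 1) 0 else
      2 * pt(-abs(rij) * sqrt((n - 2) / (1 - rij^2)), n - 2)
  }
  diag(r) <- 1
  list(r = r, p = p, n = nm)
}

#' Multiple factor analysis over trait groups
#'
#' MFA balances groups of variables before a global PCA: each group's columns
#' are centered and scaled to unit variance, the group block is divided by the
#' square root of its first eigenvalue (so no single group can dominate the
#' first global axis), the weighted blocks are concatenated, and a singular
#' value decomposition yields global axes, variance percentages, variable
#' loadings and row scores.
#'
#' @param table Rows = observations (species or contrasts), columns = traits.
#' @param groups Named list of character vectors of column names (e.g.
#'   `list(stem = ..., leaf = ...)`), each with >= 2 traits.
#' @param center Center columns before scaling. Use `FALSE` for contrast
#'   matrices, which are mean-zero through the origin by construction.
#' @param scale Scale columns to unit variance (correlation-style scaling;
#'   traits have heterogeneous units).
#' @return Object of class `mfa_result`: `variance_percent`, `eigenvalues`,
#'   `loadings` (orthonormal variable axes), `scores`, `group_weights`.
#' @export
mfa <- function(table, groups, center = TRUE, scale = TRUE) {
  m <- as.matrix(table)
  if (length(groups) < 1L) stop("invalid-argument: need >= 1 group")
  all_traits <- unlist(groups, use.names = FALSE)
  miss <- setdiff(all_traits, colnames(m))
  if (length(miss)) stop("schema error: trait column(s) absent: ",
                         paste(miss, collapse = ", "))
  if (any(vapply(groups, length, integer(1)) < 2L))
    stop("invalid-argument: every group needs >= 2 traits")
  m <- m[, all_traits, drop = FALSE]
  if (any(!is.finite(m)))
    stop("invalid-argument: MFA requires complete rows for grouped traits")
  n <- nrow(m)

  prep <- function(cols) {
    z <- m[, cols, drop = FALSE]
    if (center) z <- sweep(z, 2L, colMeans(z))
    if (scale) {
      s <- sqrt(colSums(z^2) / (n - 1))
      zero <- s == 0
      if (any(zero))
        stop("invalid-argument: constant trait column(s): ",
             paste(cols[zero], collapse = ", "))
      z <- sweep(z, 2L, s, "/")
    }
    z
  }
  weights <- numeric(length(groups))
  blocks <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    z <- prep(groups[[g]])
    lambda1 <- svd(z, nu = 0, nv = 0)$d[1L]^2 / (n - 1)
    weights[g] <- 1 / sqrt(lambda1)
    blocks[[g]] <- z * weights[g]
  }
  zz <- do.call(cbind, blocks)
  sv <- svd(zz)
  eig <- sv$d^2 / (n - 1)
  keep <- seq_len(sum(sv$d > sv$d[1L] * 1e-12))
  scores <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  rownames(scores) <- rownames(m)
  loadings <- sv$v[, keep, drop = FALSE]
  rownames(loadings) <- colnames(zz)
  colnames(loadings) <- colnames(scores) <- paste0("Axis", keep)
  structure(list(variance_percent = 100 * eig / sum(eig),
                 eigenvalues = eig,
                 loadings = loadings,
                 scores = scores,
                 group_weights = setNames(weights, names(groups))),
            class = "mfa_result")
}

#' @export
print.mfa_result <- function(x, ...) {
  cat("Multiple factor analysis\n")
  k <- min(5L, length(x$variance_percent))
  cat("  variance explained (%):",
      paste(sprintf("%.2f", x$variance_percent[seq_len(k)]), collapse = ", "),
      if (length(x$variance_percent) > k) "..." else "", "\n")
  cat("  group weights (1/sqrt(lambda1)):",
      paste(sprintf("%s=%.4g", names(x$group_weights), x$group_weights),
            collapse = ", "), "\n")
  invisible(x)
}

#' Nested variance components for one trait
#'
#' Hierarchical (species / individual-within-species / twig-within-individual)
#' variance partition by the method of moments on nested ANOVA mean squares.
#' In the balanced case with `m` individuals per species and `k` twigs per
#' individual: `sigma2_twig = MS_twig`,
#' `sigma2_ind = (MS_ind - MS_twig) / k`, and
#' `sigma2_species = (MS_species - MS_ind) / (k m)`. Unbalanced designs use
#' harmonic-mean group sizes. Negative estimates are truncated to zero and
#' percentages renormalized (classical convention).
#'
#' @param twigs Twig-level data frame with `species` and `individual` columns.
#' @param trait Name of the trait column to partition (use log10 values for
#'   multiplicative traits).
#' @return List of class `varcomp`: `sigma2` (species, individual, twig),
#'   `percent`, `mean_squares`, `all_equal` flag.
#' @export
nested_varcomp <- function(twigs, trait) {
  if (!all(c("species", "individual", trait) %in% names(twigs)))
    stop("schema error: need 'species', 'individual' and '", trait, "' columns")
  y <- twigs[[trait]]
  if (any(!is.finite(y))) stop("invalid-argument: non-finite trait values")
  sp <- as.character(twigs$species)
  ind <- paste(sp, twigs$individual, sep = "/")
  if (length(unique(sp)) < 2L)
    stop("invalid-argument: variance partition needs >= 2 species")

  gmean <- mean(y)
  sp_mean <- tapply(y, sp, mean)
  ind_mean <- tapply(y, ind, mean)
  ind_sp <- tapply(sp, ind, `[`, 1L)
  n_sp <- tapply(y, sp, length)              # twigs per species
  n_ind <- tapply(y, ind, length)            # twigs per individual
  a <- length(sp_mean)
  b <- length(ind_mean)
  N <- length(y)

  ss_sp <- sum(n_sp * (sp_mean - gmean)^2)
  ss_ind <- sum(n_ind * (ind_mean - sp_mean[ind_sp])^2)
  ss_twig <- sum((y - ind_mean[ind])^2)
  ms_sp <- ss_sp / (a - 1)
  ms_ind <- if (b - a > 0) ss_ind / (b - a) else 0
  ms_twig <- if (N - b > 0) ss_twig / (N - b) else 0

  k_twig <- 1 / mean(1 / n_ind)                          # harmonic mean twigs/ind
  inds_per_sp <- tapply(ind_sp, ind_sp, length)
  k_ind <- 1 / mean(1 / inds_per_sp)                     # harmonic mean inds/species

  s2_twig <- ms_twig
  s2_ind <- max((ms_ind - ms_twig) / k_twig, 0)
  s2_sp <- max((ms_sp - ms_ind) / (k_twig * k_ind), 0)
  total <- s2_sp + s2_ind + s2_twig
  all_equal <- total == 0
  pct <- if (all_equal) c(0, 0, 0) else
    100 * c(s2_sp, s2_ind, s2_twig) / total
  structure(list(sigma2 = c(species = s2_sp, individual = s2_ind,
                            twig = s2_twig),
                 percent = setNames(pct, c("species", "individual", "twig")),
                 mean_squares = c(species = ms_sp, individual = ms_ind,
                                  twig = ms_twig),
                 k = c(twig = k_twig, individual = k_ind),
                 all_equal = all_equal),
            class = "varcomp")
}

#' @export
print.varcomp <- function(x, ...) {
  cat("Nested variance components\n")
  lev <- names(x$sigma2)
  for (i in seq_along(lev))
    cat(sprintf("  %-10s sigma^2 = %.4g (%.1f%%)\n",
                lev[i], x$sigma2[i], x$percent[i]))
  if (x$all_equal) cat("  note: all values identical; percentages set to 0\n")
  invisible(x)
}
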