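.free_traits <- c("SA", "SM", "TLA", "LeM", "PA", "IPM", "LI", "Dh", "Ktheo",
                  "WD", "MOE", "SWC", "LT", "UET", "PT", "SP", "LET", "SS", "SD")

.default_root_state <- c(
  SA = 0.9, SM = 0.4, TLA = 2.6, LeM = 0.6, PA = 0.5, IPM = -1.3, LI = 0.6,
  Dh = 1.6, Ktheo = 0.7, WD = -0.3, MOE = 3.5, SWC = 1.85,
  LT = 2.3, UET = 1.3, PT = 1.9, SP = 1.8, LET = 1.15, SS = 1.35, SD = 2.4)

.default_rates <- c(
  SA = 0.08, SM = 0.08, TLA = 0.09, LeM = 0.09, PA = 0.08, IPM = 0.10,
  LI = 0.06, Dh = 0.02, Ktheo = 0.06, WD = 0.012, MOE = 0.02, SWC = 0.008,
  LT = 0.02, UET = 0.02, PT = 0.02, SP = 0.02, LET = 0.02, SS = 0.01,
  SD = 0.04)

.default_exponents <- function() {
  data.frame(y = c("TLA", "LeM", "SM", "PA", "IPM"),
             x = c("SA", "TLA", "SA", "TLA", "LeM"),
             beta = c(1.009, 1.123, 1.20, 0.90, 1.21),
             r2 = c(0.91, 0.90, 0.85, 0.75, 0.88))
}

.default_tradeoffs <- function() {
  data.frame(a = c("LI", "Dh", "Ktheo", "WD", "MOE", "SWC", "SS"),
             b = c("SA", "SA", "Dh", "Ktheo", "WD", "WD", "SD"),
             r = c(-0.83, 0.80, 0.85, -0.65, 0.75, -0.70, -0.60))
}

#' Configuration of the synthetic twig-survey generator
#'
#' Describes a simulated common-garden survey: a Yule species phylogeny,
#' species-level log10 trait means evolved by multivariate Brownian motion
#' (BM) with imposed allometric exponents and trade-off correlations, and
#' nested individual- and twig-level multiplicative measurement noise. The
#' defaults emulate the 28-species design the package targets: 3 individuals
#' per species, 3-5 twigs per individual (roughly 250 twigs), within-species
#' variation well under 20%.
#'
#' Allometric structure is imposed after BM simulation: for a pair `(y, x)`
#' with exponent `beta` and target `r2`,
#' `y = root_y + beta*sqrt(r2)*(x - root_x) + eps`, where `eps` is the trait's
#' own (rescaled) BM deviate with sd `|beta|*sd(x)*sqrt(1 - r2)`. This makes
#' the *population SMA slope* exactly `beta` and the population R^2 exactly
#' `r2`, while residuals stay phylogenetically structured. Trade-off entries
#' `(a, b, r)` reuse the same machinery with
#' `beta = sign(r)*sd(a)/sd(b)`, preserving trait `a`'s marginal variance.
#'
#' @param n_species Number of species (tree tips), >= 3.
#' @param n_individuals Individuals sampled per species.
#' @param n_twigs_min,n_twigs_max Twigs per individual (drawn uniformly).
#' @param root_state Named vector of log10 trait means at the tree root.
#' @param bm_rates Named vector of BM rates (log10^2 per unit depth; diagonal
#'   rate matrix) or a full symmetric PSD rate matrix with dimnames.
#' @param allometric_exponents Data frame `y`, `x`, `beta`, `r2`.
#' @param tradeoff_correlations Data frame `a`, `b`, `r`.
#' @param noise_sd_individual,noise_sd_twig Log10-scale SDs of the nested
#'   multiplicative measurement noise.
#' @param vessel_cv Coefficient of variation of vessel diameters within a stem.
#' @param vessel_aspect Range of vessel ellipse aspect ratios a/b.
#' @param sapwood_fraction Sapwood area as a fraction of stem area.
#' @param vessel_window_mm2 Target analyzed xylem window, mm^2.
#' @param segment_length_mm Gravimetric/bending stem segment length, mm.
#' @param wall_density_g_cm3 Cell-wall density bounding wood density, g cm^-3.
#' @param seed Integer seed; all randomness flows from it through one stream
#'   (tree, then species traits, then species-by-species measurement noise).
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 28, n_individuals = 3,
                              n_twigs_min = 3, n_twigs_max = 5,
                              root_state = .default_root_state,
                              bm_rates = .default_rates,
                              allometric_exponents = .default_exponents(),
                              tradeoff_correlations = .default_tradeoffs(),
                              noise_sd_individual = 0.05,
                              noise_sd_twig = 0.08,
                              vessel_cv = 0.25,
                              vessel_aspect = c(1.05, 1.5),
                              sapwood_fraction = 0.8,
                              vessel_window_mm2 = 0.35,
                              segment_length_mm = 60,
                              wall_density_g_cm3 = 1.53,
                              seed = 1L) {
  if (!is.numeric(n_species) || n_species < 3)
    stop("invalid-argument: n_species must be >= 3")
  if (noise_sd_individual < 0 || noise_sd_twig < 0)
    stop("invalid-argument: noise SDs must be >= 0")
  if (n_twigs_min < 1 || n_twigs_max < n_twigs_min)
    stop("invalid-argument: need 1 <= n_twigs_min <= n_twigs_max")
  traits <- names(root_state)
  if (is.null(traits)) stop("invalid-argument: root_state must be named")
  if (is.matrix(bm_rates)) {
    R <- bm_rates
    if (!isTRUE(all.equal(R, t(R))))
      stop("invalid-argument: bm_rate_matrix must be symmetric")
    if (!identical(sort(rownames(R)), sort(traits)))
      stop("invalid-argument: bm_rate_matrix dimnames must match root_state")
    R <- R[traits, traits]
  } else {
    if (!identical(sort(names(bm_rates)), sort(traits)))
      stop("invalid-argument: bm_rates names must match root_state")
    R <- diag(bm_rates[traits], length(traits))
    dimnames(R) <- list(traits, traits)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1))
    stop("invalid-argument: bm_rate_matrix must be positive semi-definite")
  check_pairs <- function(df, c1, c2) {
    if (is.null(df) || nrow(df) == 0) return(invisible())
    bad <- setdiff(c(df[[c1]], df[[c2]]), traits)
    if (length(bad)) stop("invalid-argument: unknown trait(s) in pair spec: ",
                          paste(unique(bad), collapse = ", "))
  }
  check_pairs(allometric_exponents, "y", "x")
  check_pairs(tradeoff_correlations, "a", "b")
  if (!is.null(allometric_exponents) && nrow(allometric_exponents) &&
      (any(allometric_exponents$r2 < 0) || any(allometric_exponents$r2 > 1)))
    stop("invalid-argument: r2 targets must lie in [0, 1]")
  if (!is.null(tradeoff_correlations) && nrow(tradeoff_correlations) &&
      any(abs(tradeoff_correlations$r) > 1))
    stop("invalid-argument: trade-off correlations must lie in [-1, 1]")
  structure(list(n_species = as.integer(n_species),
                 n_individuals = as.integer(n_individuals),
                 n_twigs_min = as.integer(n_twigs_min),
                 n_twigs_max = as.integer(n_twigs_max),
                 traits = traits, root_state = root_state,
                 bm_rate_matrix = R,
                 allometric_exponents = allometric_exponents,
                 tradeoff_correlations = tradeoff_correlations,
                 noise_sd_individual = noise_sd_individual,
                 noise_sd_twig = noise_sd_twig,
                 vessel_cv = vessel_cv, vessel_aspect = vessel_aspect,
                 sapwood_fraction = sapwood_fraction,
                 vessel_window_mm2 = vessel_window_mm2,
                 segment_length_mm = segment_length_mm,
                 wall_density_g_cm3 = wall_density_g_cm3,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a Yule (pure-birth) species phylogeny
#'
#' Constant-rate pure-birth construction: starting from two lineages, waiting
#' times are Exp(k) for k extant lineages and a uniformly chosen lineage
#' splits, until `n_species` tips exist; a final Exp(n) increment gives the
#' youngest tips positive terminal branches. The tree is ultrametric and
#' rescaled to root-to-tip depth 1 so BM rates are per total depth. Tip
#' labels are `sp01`, `sp02`, ...
#'
#' @param n_species Number of tips, >= 3.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return An `ape::phylo` tree.
#' @export
simulate_tree <- function(n_species, seed = NULL) {
  if (!is.numeric(n_species) || n_species < 3)
    stop("invalid-argument: n_species must be >= 3")
  n <- as.integer(n_species)
  if (!is.null(seed)) set.seed(as.integer(seed))

  parent <- c(NA_integer_, 1L, 1L) # local ids; 1 = root, born at time 0
  btime <- c(0, 0, 0)
  active <- c(2L, 3L)
  t <- 0
  while (length(active) < n) {
    k <- length(active)
    t <- t + rexp(1L, rate = k)
    i <- active[sample.int(k, 1L)]
    id1 <- length(parent) + 1L
    parent <- c(parent, i, i)
    btime <- c(btime, t, t)
    active <- c(active[active != i], id1, id1 + 1L)
  }
  t_end <- t + rexp(1L, rate = n)

  m <- length(parent)
  is_tip <- !(seq_len(m) %in% parent[-1L])
  tip_ids <- sort(which(is_tip))
  int_ids <- sort(which(!is_tip)) # root (id 1) first
  map <- integer(m)
  map[tip_ids] <- seq_len(n)
  map[int_ids] <- n + seq_along(int_ids)
  end_time <- rep(t_end, m)
  for (j in seq(2L, m)) end_time[parent[j]] <- btime[j] # split time of parent
  child <- seq(2L, m)
  edge <- cbind(map[parent[child]], map[child])
  elen <- (end_time[child] - btime[child]) / t_end
  tr <- structure(list(edge = edge, edge.length = elen,
                       tip.label = sprintf("sp%02d", seq_len(n)),
                       Nnode = n - 1L),
                  class = "phylo")
  validate_phylogeny(tr)
}

# population sd of each trait's BM deviate at depth-1 tips
.bm_sigma <- function(R) sqrt(pmax(diag(R), 0))

# matrix square root for a PSD rate matrix (chol fails on singular matrices)
.psd_sqrt <- function(R) {
  e <- eigen(R, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate species-level trait means on a phylogeny
#'
#' Multivariate Brownian motion of log10 traits along the tree (per-branch
#' increment covariance = branch length x rate matrix), followed by the
#' imposition of the configured allometric exponents and trade-off
#' correlations (see [simulation_config()]). When the table carries the
#' standard trait set, the derived species columns are filled in: `SLA` from
#' `TLA`/`LeM`; an integer species leaf count from `LI*SM` (with `LI`
#' re-derived so count/`SM` is exact); `ILA`, `ILM` from the leaf count; `VD`
#' and `VF` from `Dh` and `Ktheo` (the vessel system is over-determined, so
#' density and fraction follow from diameter, conductivity and the
#' Hagen-Poiseuille law); `SWC` clamped at 98% (its formula bound is 100%).
#'
#' @param tree Ultrametric phylogeny (depth 1 for rates to be interpretable),
#'   or `NULL` for phylogenetically independent species (the star-phylogeny
#'   limit: iid Gaussian deviates at depth 1, `config$n_species` tips).
#' @param config A [simulation_config()].
#' @param seed Optional seed; `NULL` continues the current stream.
#' @return Species-by-trait data frame on the natural measurement scale
#'   (rownames = tip labels), with attribute `n_leaves` when the standard
#'   trait set is present.
#' @export
simulate_species_traits <- function(tree, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  traits <- config$traits
  p <- length(traits)
  R <- config$bm_rate_matrix
  S <- .psd_sqrt(R)

  if (is.null(tree)) {
    ntip <- config$n_species
    dev0 <- t(S %*% matrix(rnorm(p * ntip), p, ntip))
    tip_labels <- sprintf("sp%02d", seq_len(ntip))
  } else {
    validate_phylogeny(tree)
    ntip <- length(tree$tip.label)
    if (ntip < 2L) stop("invalid-argument: need >= 2 tips")
    po <- stats::reorder(tree, "postorder")
    edge <- po$edge
    elen <- po$edge.length
    val <- matrix(0, ntip + tree$Nnode, p) # BM deviates; root = 0
    for (i in rev(seq_len(nrow(edge)))) {  # reverse postorder: parents first
      val[edge[i, 2L], ] <- val[edge[i, 1L], ] +
        sqrt(elen[i]) * as.numeric(S %*% rnorm(p))
    }
    dev0 <- val[seq_len(ntip), , drop = FALSE]
    tip_labels <- tree$tip.label
  }
  colnames(dev0) <- traits
  M <- sweep(dev0, 2L, -config$root_state[traits])
  rownames(M) <- tip_labels
  sigma0 <- setNames(.bm_sigma(R), traits)
  sigma_eff <- sigma0
  root <- config$root_state

  impose <- function(yname, xname, beta, r2) {
    if (sigma_eff[xname] <= 0)
      stop("invalid-argument: trait '", xname, "' needs a positive BM rate ",
           "to drive an imposed relationship")
    rho <- sqrt(r2)
    sd_eps <- abs(beta) * sigma_eff[xname] * sqrt(max(1 - r2, 0))
    eps <- if (sd_eps == 0) 0 else {
      if (sigma0[yname] <= 0)
        stop("invalid-argument: trait '", yname, "' needs a positive BM rate ",
             "to carry residual noise (target r2 < 1)")
      dev0[, yname] / sigma0[yname] * sd_eps
    }
    M[, yname] <<- root[yname] + beta * rho * (M[, xname] - root[xname]) + eps
    sigma_eff[yname] <<- abs(beta) * sigma_eff[xname]
  }
  ae <- config$allometric_exponents
  if (!is.null(ae) && nrow(ae))
    for (i in seq_len(nrow(ae))) impose(ae$y[i], ae$x[i], ae$beta[i], ae$r2[i])
  tc <- config$tradeoff_correlations
  if (!is.null(tc) && nrow(tc)) {
    for (i in seq_len(nrow(tc))) {
      beta <- sign(tc$r[i]) * sigma_eff[tc$a[i]] / sigma_eff[tc$b[i]]
      impose(tc$a[i], tc$b[i], beta, tc$r[i]^2)
    }
  }
  if (any(!is.finite(M))) stop("internal: non-finite simulated trait values")
  out <- as.data.frame(10^M)

  if (all(.free_traits %in% traits)) {
    out$SWC <- pmin(out$SWC, 98)
    out$WD <- pmin(out$WD, config$wall_density_g_cm3 * 0.95)
    n_leaves <- pmax(1, round(out$LI * out$SM))
    out$LI <- n_leaves / out$SM
    out$ILA <- out$TLA / n_leaves
    out$ILM <- out$LeM / n_leaves
    out$SLA <- (out$TLA * .units$cm2_to_m2) / (out$LeM * .units$g_to_kg)
    out$VD <- .vd_from_k(out$Ktheo, out$Dh)
    out$VF <- .vf_expected(out$VD, out$Dh, config$vessel_cv,
                           config$vessel_aspect)
    codes <- c("SA", "SM", "Dh", "VD", "VF", "Ktheo", "WD", "SWC", "MOE",
               "PA", "IPM", "TLA", "ILA", "LeM", "ILM", "SLA", "LI", "LT",
               "UET", "PT", "SP", "LET", "SS", "SD")
    out <- out[codes]
    attr(out, "n_leaves") <- setNames(n_leaves, rownames(out))
  }
  out
}

# vessel density (mm^-2) implied by K_theo (kg m^-1 MPa^-1 s^-1) and Dh (um)
.vd_from_k <- function(K, Dh_um, constants = physical_constants()) {
  d_m <- Dh_um * .units$um_to_m
  K * 128 * constants$mu_water / (pi * constants$rho_water * d_m^4) * 1e-6
}

# expected vessel fraction given VD, Dh and the within-stem diameter spread:
# the generator rescales draws so mean(D^4) = Dh^4, which shrinks mean(D^2)
# by exp(-2*sigma_log^2) for a lognormal shape; the ellipse aspect q inflates
# lumen area by sqrt((q^2+1)/(2q)) relative to a circle of equal D.
.vf_expected <- function(VD_mm2, Dh_um, cv, aspect) {
  s2 <- log(1 + cv^2)
  qs <- seq(aspect[1L], aspect[2L], length.out = 200L)
  gbar <- mean(sqrt((qs^2 + 1) / (2 * qs)))
  VD_mm2 * (pi / 4) * Dh_um^2 * exp(-2 * s2) * gbar * .units$um2_to_mm2
}

#' Expand species means into nested noisy measurement tables
#'
#' Adds multiplicative (log10-additive) individual- then twig-level noise to
#' every free trait and renders the four raw tables the derivation pipeline
#' consumes: a twig architecture table, a long-format vessel table (semi-axes
#' drawn so that recomputing `Dh`, `VD` and `Ktheo` from the table recovers
#' the twig targets exactly, and `VF` within vessel-sampling error), a
#' gravimetric table consistent with target `WD` and `SWC`, and a three-point
#' bending table consistent with target `MOE`.
#'
#' @param species_means Output of [simulate_species_traits()] (standard trait
#'   set required).
#' @param config The [simulation_config()] used to generate it.
#' @param tree Optional phylogeny carried into the dataset.
#' @param seed Optional seed; `NULL` continues the current stream.
#' @return Object of class `synthetic_dataset`: list with `tree`,
#'   `species_means`, `twig_table`, `vessel_table`, `gravimetric_table`,
#'   `bending_table`, `truth` (the config).
#' @export
expand_to_measurements <- function(species_means, config, tree = NULL,
                                   seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  need <- c("SA", "SM", "TLA", "LeM", "PA", "IPM", "LI", "Dh", "Ktheo", "WD",
            "MOE", "SWC", "LT", "UET", "PT", "SP", "LET", "SS", "SD")
  miss <- setdiff(need, names(species_means))
  if (length(miss)) stop("schema error: species means missing trait(s): ",
                         paste(miss, collapse = ", "))
  if (!is.null(seed)) set.seed(as.integer(seed))
  species <- rownames(species_means)
  noise_traits <- c(need, "VD")
  # Dh varies little within a species; K_theo follows per twig from (Dh, VD)
  # via the fourth-power law, which would otherwise amplify Dh noise 4-fold
  sd_scale <- setNames(rep(1, length(noise_traits)), noise_traits)
  sd_scale["Dh"] <- 0.25
  sd_i <- config$noise_sd_individual * sd_scale
  sd_t <- config$noise_sd_twig * sd_scale
  s2log <- log(1 + config$vessel_cv^2)
  defl_rel <- 0.25 * config$noise_sd_twig # deflection noise; 0 when noise off

  twig_rows <- list()
  vessel_rows <- list()
  grav_rows <- list()
  bend_rows <- list()
  for (sp in species) {
    mu <- species_means[sp, noise_traits]
    for (ind in seq_len(config$n_individuals)) {
      mult_i <- 10^rnorm(length(noise_traits), 0, sd_i)
      ntw <- if (config$n_twigs_max > config$n_twigs_min)
        sample(config$n_twigs_min:config$n_twigs_max, 1L) else
        config$n_twigs_min
      for (tw in seq_len(ntw)) {
        v <- setNames(as.numeric(mu) * mult_i *
                        10^rnorm(length(noise_traits), 0, sd_t),
                      noise_traits)
        stem_id <- paste(sp, ind, tw, sep = ".")
        n_leaf <- max(1, round(v[["LI"]] * v[["SM"]]))
        twig_rows[[stem_id]] <- data.frame(
          species = sp, individual = ind, twig = tw, stem_id = stem_id,
          stem_area_mm2 = v[["SA"]], stem_mass_g = v[["SM"]],
          leaf_count = n_leaf, total_lamina_area_cm2 = v[["TLA"]],
          total_lamina_mass_g = v[["LeM"]],
          total_petiole_mass_g = v[["IPM"]] * n_leaf,
          petiole_area_mm2 = v[["PA"]],
          LT = v[["LT"]], UET = v[["UET"]], PT = v[["PT"]], SP = v[["SP"]],
          LET = v[["LET"]], SS = v[["SS"]], SD = v[["SD"]])

        # vessels: twig K_theo follows from the noised (Dh, VD) pair by the
        # Hagen-Poiseuille law; diameters rescaled so the fourth-power mean
        # is exact; window area set so count/area is exact
        vd <- v[["VD"]]
        n_v <- max(30L, as.integer(round(vd * config$vessel_window_mm2)))
        a_an <- n_v / vd
        z <- rlnorm(n_v, 0, sqrt(s2log))
        d <- z * v[["Dh"]] / mean(z^4)^0.25
        q <- runif(n_v, config$vessel_aspect[1L], config$vessel_aspect[2L])
        b_semi <- d * ((q^2 + 1) / (32 * q^3))^0.25
        vessel_rows[[stem_id]] <- data.frame(
          stem_id = stem_id, a_um = q * b_semi, b_um = b_semi,
          analyzed_xylem_area_mm2 = a_an,
          sapwood_area_mm2 = config$sapwood_fraction * v[["SA"]])

        # gravimetric: segment volume from stem area and length; pore space
        # bounded by cell-wall density
        wd <- min(v[["WD"]], config$wall_density_g_cm3 * 0.95)
        swc <- min(v[["SWC"]], 99.9)
        vol <- v[["SA"]] * config$segment_length_mm / 1000 # mm^3 -> cm^3
        dw <- wd * vol
        sw <- dw + vol * (1 - wd / config$wall_density_g_cm3) * 0.9982
        fw <- dw + swc / 100 * (sw - dw)
        grav_rows[[stem_id]] <- data.frame(
          stem_id = stem_id, fw_g = fw, sw_g = sw, dw_g = dw,
          fresh_volume_cm3 = vol)

        # bending: deflections from MOE via delta = F L^3 / (48 EI)
        dia <- 2 * sqrt(v[["SA"]] / pi)
        span <- 26 * dia
        inertia <- pi * dia^4 / 64
        slope <- span^3 / (48 * v[["MOE"]] * inertia)
        f_max <- span / (30 * slope)
        loads <- seq_len(5L) / 5 * f_max
        defl <- slope * loads * (1 + rnorm(5L, 0, defl_rel))
        bend_rows[[stem_id]] <- data.frame(
          stem_id = stem_id, span_mm = span, diameter_mm = dia,
          load_n = loads, deflection_mm = defl)
      }
    }
  }
  ds <- list(tree = tree, species_means = species_means,
             twig_table = do.call(rbind, twig_rows),
             vessel_table = do.call(rbind, vessel_rows),
             gravimetric_table = do.call(rbind, grav_rows),
             bending_table = do.call(rbind, bend_rows),
             truth = config)
  rownames(ds$twig_table) <- rownames(ds$vessel_table) <-
    rownames(ds$gravimetric_table) <- rownames(ds$bending_table) <- NULL
  structure(ds, class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic twig survey\n")
  cat(sprintf("  %d species, %d twigs, %d vessel measurements\n",
              nrow(x$species_means), nrow(x$twig_table), nrow(x$vessel_table)))
  invisible(x)
}

#' Simulate a complete synthetic dataset
#'
#' Seeds the RNG once from `config$seed` and runs, in one documented stream
#' order, [simulate_tree()], [simulate_species_traits()] and
#' [expand_to_measurements()]. Identical configs give bit-identical datasets.
#'
#' @param config A [simulation_config()].
#' @return A `synthetic_dataset`.
#' @examples
#' ds <- simulate_dataset(simulation_config(n_species = 5, seed = 42))
#' head(ds$twig_table)
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  tree <- simulate_tree(config$n_species, seed = NULL)
  sm <- simulate_species_traits(tree, config, seed = NULL)
  expand_to_measurements(sm, config, tree = tree, seed = NULL)
}

#' Write a synthetic dataset to disk
#'
#' Emits the newick tree, the four raw CSV tables, the species-mean CSV and a
#' JSON truth file echoing the generating configuration.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(tree = file.path(dir, "tree.nwk"),
             species_means = file.path(dir, "species_means.csv"),
             twig = file.path(dir, "twig_table.csv"),
             vessel = file.path(dir, "vessel_table.csv"),
             gravimetric = file.path(dir, "gravimetric_table.csv"),
             bending = file.path(dir, "bending_table.csv"),
             truth = file.path(dir, "truth.json"))
  if (!is.null(dataset$tree)) write_newick(dataset$tree, paths["tree"])
  write.csv(cbind(species = rownames(dataset$species_means),
                  dataset$species_means),
            paths["species_means"], row.names = FALSE)
  write.csv(dataset$twig_table, paths["twig"], row.names = FALSE)
  write.csv(dataset$vessel_table, paths["vessel"], row.names = FALSE)
  write.csv(dataset$gravimetric_table, paths["gravimetric"], row.names = FALSE)
  write.csv(dataset$bending_table, paths["bending"], row.names = FALSE)
  truth <- dataset$truth
  truth$bm_rate_matrix <- as.data.frame(truth$bm_rate_matrix)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(paths)
}

#' Reference scaling exponents from a published 28-species fig twig survey
#'
#' SMA slopes, R^2 and confidence intervals reported for log-log trait pairs
#' in a common-garden survey of 28 *Ficus* tree species -- the study system
#' this package's default simulation emulates. Used to parameterize
#' slope-recovery experiments and the default analysis pair list; they are
#' inputs to simulations, never asserted as outputs.
#'
#' @return Data frame with columns `y`, `x`, `r2`, `slope`, `ci_low`,
#'   `ci_high`, `p`.
#' @export
reference_exponents <- function() {
  data.frame(
    y = c("TLA", "ILA", "LeM", "ILM", "TLA", "ILA", "LeM", "ILM", "ILA",
          "ILM", "ILA", "ILM", "TLA", "ILA", "LeM", "ILM", "LeM", "ILM"),
    x = c("SM", "SM", "SM", "SM", "SA", "SA", "SA", "SA", "PA", "PA",
          "IPM", "IPM", "LI", "LI", "LI", "LI", "TLA", "ILA"),
    r2 = c(0.80, 0.68, 0.87, 0.70, 0.91, 0.84, 0.89, 0.77, 0.72, 0.85,
           0.83, 0.88, 0.69, 0.77, 0.86, 0.87, 0.90, 0.90),
    slope = c(0.870, 0.810, 0.978, 0.941, 1.009, 0.939, 1.133, 1.090, 0.958,
              1.102, 0.720, 0.828, -0.976, -0.908, -1.096, -1.055, 1.123,
              1.150),
    ci_low = c(0.728, 0.647, 0.845, 0.756, 0.892, 0.800, 0.991, 0.900,
               0.775, 0.942, 0.611, 0.721, -1.219, -1.102, -1.277, -1.219,
               0.991, 1.011),
    ci_high = c(1.041, 1.014, 1.131, 1.170, 1.141, 1.101, 1.295, 1.321,
                1.184, 1.288, 0.848, 0.950, -0.781, -0.748, -0.941, -0.912,
                1.273, 1.308),
    p = c(0.123, 0.065, 0.752, 0.573, 0.885, 0.424, 0.066, 0.365, 0.686,
          0.213, 0.000, 0.009, 0.823, 0.318, 0.230, 0.459, 0.067, 0.034))
}

#' Default SMA pair list (size-size pairs against +1, size-LI against -1)
#'
#' @return Data frame `y`, `x`, `b0` matching [reference_exponents()].
#' @export
default_sma_pairs <- function() {
  ref <- reference_exponents()
  data.frame(y = ref$y, x = ref$x, b0 = ifelse(ref$slope < 0, -1, 1))
}

#' Default MFA trait grouping: 11 stem/petiole vs 13 leaf traits
#'
#' @return Named list of trait-code vectors.
#' @export
default_trait_groups <- function() {
  list(stem = c("SA", "SM", "Dh", "VD", "VF", "Ktheo", "WD", "SWC", "MOE",
                "PA", "IPM"),
       leaf = c("TLA", "ILA", "LeM", "ILM", "SLA", "LI", "LT", "UET", "PT",
                "SP", "LET", "SS", "SD"))
}

#' Monte-Carlo SMA slope-recovery experiment
#'
#' Repeatedly simulates `n_species` species-level values of two traits linked
#' by the requested SMA exponent `beta` at target `r2`, fits the SMA slope,
#' and tests it against `b0`. This is the parameter-recovery harness used to
#' check that generative exponents (e.g. literature values from
#' [reference_exponents()]) are recovered by the estimator.
#'
#' `tree_model = "star"` (default) draws independent species deviates -- the
#' setting under which SMA sampling theory (CIs, tests) is exact.
#' `tree_model = "yule"` evolves the traits on a fresh Yule tree per
#' replicate; phylogenetic correlation among tips then widens the sampling
#' spread beyond the iid theory (slope recovery still holds, CI coverage does
#' not).
#'
#' @param beta Generative SMA exponent.
#' @param r2 Target coefficient of determination.
#' @param n_reps Number of replicate datasets.
#' @param n_species Species per dataset.
#' @param seed Integer seed.
#' @param b0 Hypothesized slope for the isometry test (sign-matched to
#'   `beta` by default).
#' @param rate BM rate of the two traits.
#' @param tree_model `"star"` (independent species) or `"yule"`.
#' @return List: `mean_slope`, `sd_slope`, `coverage` (fraction of 95% CIs
#'   containing `beta`), `reject_frac` (isometry test at alpha = 0.05),
#'   `slopes`.
#' @export
sma_recovery_experiment <- function(beta, r2, n_reps = 500, n_species = 28,
                                    seed = 1L, b0 = sign(beta), rate = 0.08,
                                    tree_model = c("star", "yule")) {
  tree_model <- match.arg(tree_model)
  cfg <- simulation_config(
    n_species = n_species,
    root_state = c(Y = 0, X = 0), bm_rates = c(Y = rate, X = rate),
    allometric_exponents = data.frame(y = "Y", x = "X", beta = beta, r2 = r2),
    tradeoff_correlations = NULL, seed = seed)
  set.seed(as.integer(seed))
  slopes <- numeric(n_reps)
  cover <- logical(n_reps)
  reject <- logical(n_reps)
  for (i in seq_len(n_reps)) {
    tree <- if (tree_model == "yule") simulate_tree(n_species, seed = NULL)
            else NULL
    m <- simulate_species_traits(tree, cfg, seed = NULL)
    fit <- sma_fit(log10(m$X), log10(m$Y), b0 = b0)
    slopes[i] <- fit$slope
    cover[i] <- fit$ci_low <= beta && beta <= fit$ci_high
    reject[i] <- fit$p_value < 0.05
  }
  list(mean_slope = mean(slopes), sd_slope = sd(slopes),
       coverage = mean(cover), reject_frac = mean(reject), slopes = slopes)
}
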