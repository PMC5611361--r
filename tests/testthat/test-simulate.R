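test_that("config validation enforces the documented invariants", {
  expect_error(simulation_config(n_species = 2), "n_species")
  expect_error(simulation_config(noise_sd_twig = -0.1), "noise SDs")
  badR <- matrix(c(1, 2, 2, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(simulation_config(root_state = c(A = 0, B = 0), bm_rates = badR,
                                 allometric_exponents = NULL,
                                 tradeoff_correlations = NULL),
               "positive semi-definite")
  expect_error(simulation_config(
    root_state = c(A = 0), bm_rates = c(A = 1),
    allometric_exponents = data.frame(y = "A", x = "Z", beta = 1, r2 = 1),
    tradeoff_correlations = NULL), "unknown trait")
})

test_that("Yule trees: shape, determinism, cherry expectation", {
  tr <- simulate_tree(3, seed = 1)
  expect_equal(length(tr$tip.label), 3)
  expect_equal(tr$Nnode, 2)
  expect_true(ape::is.ultrametric(tr, tol = 1e-10))
  expect_equal(max(ape::node.depth.edgelength(tr)), 1, tolerance = 1e-12)
  expect_equal(tr$tip.label, c("sp01", "sp02", "sp03"))

  # determinism contract
  expect_identical(write_newick(simulate_tree(12, seed = 7)),
                   write_newick(simulate_tree(12, seed = 7)))
  expect_false(identical(write_newick(simulate_tree(12, seed = 7)),
                         write_newick(simulate_tree(12, seed = 8))))
  expect_error(simulate_tree(2), "invalid-argument")

  # mean cherry count over 200 trees vs an independent ERM process oracle
  # (both should sit near the Yule expectation n/3 = 9.33 for n = 28)
  set.seed(50)
  cherries <- replicate(200, count_cherries(simulate_tree(28, seed = NULL)))
  oracle <- erm_cherry_oracle(28, n_reps = 2000)
  expect_equal(mean(cherries), oracle, tolerance = 0.05)
  expect_equal(mean(cherries), 28 / 3, tolerance = 0.05)
})

test_that("BM simulation: zero-variance limit and 2-tip variance oracle", {
  cfg0 <- simulation_config(n_species = 4, root_state = c(A = 2),
                            bm_rates = c(A = 0), allometric_exponents = NULL,
                            tradeoff_correlations = NULL, seed = 1)
  tr <- simulate_tree(4, seed = 2)
  m <- simulate_species_traits(tr, cfg0, seed = 3)
  expect_equal(m$A, rep(100, 4)) # 10^2: all tips at the root state

  # closed-form BM: tip difference on a 2-tip depth-1 tree has variance 2
  t2 <- parse_newick("(A:1,B:1);")
  cfg1 <- simulation_config(n_species = 3, root_state = c(A = 0),
                            bm_rates = c(A = 1), allometric_exponents = NULL,
                            tradeoff_correlations = NULL, seed = 1)
  set.seed(11)
  diffs <- replicate(2000, {
    m <- simulate_species_traits(t2, cfg1, seed = NULL)
    diff(log10(m$A))
  })
  expect_equal(var(diffs), 2, tolerance = 0.15)
})

test_that("imposed exponent is exact at r2 = 1 and recovered in CI otherwise", {
  tr <- simulate_tree(28, seed = 4)
  m <- simulate_species_traits(tr, pair_config(beta = 1, r2 = 1), seed = 5)
  fit <- sma_fit(log10(m$X), log10(m$Y))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # beta within its 95% CI in >= 90% of 500 independent-species datasets
  rec <- sma_recovery_experiment(1.25, 0.8, n_reps = 500, seed = 6)
  expect_gte(rec$coverage, 0.90)
  expect_equal(rec$mean_slope, 1.25, tolerance = 0.03)
})

test_that("seed determinism: identical config gives bit-identical datasets", {
  cfg <- simulation_config(n_species = 5, seed = 123)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$species_means, d2$species_means)
  expect_identical(d1$twig_table, d2$twig_table)
  expect_identical(d1$vessel_table, d2$vessel_table)
  expect_identical(d1$gravimetric_table, d2$gravimetric_table)
  expect_identical(d1$bending_table, d2$bending_table)
  expect_identical(write_newick(d1$tree), write_newick(d2$tree))
  d3 <- simulate_dataset(simulation_config(n_species = 5, seed = 124))
  expect_false(identical(d1$twig_table, d3$twig_table))
})

test_that("zero-noise round trip: derived species means equal the truth", {
  cfg0 <- simulation_config(n_species = 6, noise_sd_individual = 0,
                            noise_sd_twig = 0, n_twigs_min = 3,
                            n_twigs_max = 3, seed = 31)
  ds <- simulate_dataset(cfg0)
  tw <- derive_twig_traits(ds$twig_table)
  tw <- merge(tw, derive_stem_hydraulics(ds$vessel_table), by = "stem_id")
  tw <- merge(tw, derive_stem_composition(ds$gravimetric_table), by = "stem_id")
  tw <- merge(tw, derive_stem_bending(ds$bending_table)[c("stem_id", "MOE")],
              by = "stem_id")
  sm <- aggregate_species_means(tw)
  truth <- ds$species_means[rownames(sm), colnames(sm)]
  exact <- setdiff(colnames(sm), "VF")
  expect_equal(as.matrix(sm[exact]), as.matrix(truth[exact]),
               tolerance = 1e-8)
  # VF carries vessel-shape sampling error (second vs fourth moment)
  expect_equal(sm$VF, truth$VF, tolerance = 0.1)
})

test_that("generated designs respect the sampling-protocol contracts", {
  ds <- simulate_dataset(simulation_config(seed = 17))
  tw <- ds$twig_table
  expect_equal(length(unique(tw$species)), 28)
  counts <- tapply(tw$twig, paste(tw$species, tw$individual), max)
  expect_true(all(counts >= 3 & counts <= 5))
  expect_equal(length(unique(paste(tw$species, tw$individual))), 28 * 3)
  expect_true(all(table(ds$vessel_table$stem_id) >= 30))
  expect_true(all(ds$vessel_table$a_um > 0))
  # every species in every table appears on the tree
  expect_true(all(tw$species %in% ds$tree$tip.label))
  expect_true(all(is.finite(as.matrix(ds$species_means))))
})

test_that("default synthetic design puts most trait variance among species", {
  ds <- simulate_dataset(simulation_config(seed = 29))
  tw <- derive_twig_traits(ds$twig_table)
  for (tr in c("SA", "TLA", "LeM")) {
    twl <- tw
    twl[[tr]] <- log10(twl[[tr]])
    vc <- nested_varcomp(twl, tr)
    expect_gt(vc$percent[["species"]], 70)
  }
})

test_that("written datasets are complete and reloadable", {
  dir <- withr::local_tempdir()
  ds <- simulate_dataset(simulation_config(n_species = 4, seed = 2))
  paths <- write_dataset(ds, dir)
  expect_true(all(file.exists(paths)))
  tr <- parse_newick(paths[["tree"]])
  expect_setequal(tr$tip.label, rownames(ds$species_means))
  vt <- read.csv(paths[["vessel"]])
  expect_equal(nrow(vt), nrow(ds$vessel_table))
  truth <- jsonlite::read_json(paths[["truth"]])
  expect_equal(truth$n_species, 4)
})
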