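# Shared fixtures and independent oracles for the test suite.

# Minimal one-row twig table with round numbers.
toy_twig_row <- function(species = "sp01", individual = 1, twig = 1,
                         stem_area_mm2 = 8, stem_mass_g = 2, leaf_count = 10,
                         total_lamina_area_cm2 = 300, total_lamina_mass_g = 2,
                         total_petiole_mass_g = 0.5, petiole_area_mm2 = 3) {
  data.frame(species = species, individual = individual, twig = twig,
             stem_area_mm2 = stem_area_mm2, stem_mass_g = stem_mass_g,
             leaf_count = leaf_count,
             total_lamina_area_cm2 = total_lamina_area_cm2,
             total_lamina_mass_g = total_lamina_mass_g,
             total_petiole_mass_g = total_petiole_mass_g,
             petiole_area_mm2 = petiole_area_mm2)
}

# Two-trait simulation config for allometry-structure experiments.
pair_config <- function(beta, r2, n_species = 28, rate = 0.08, seed = 1L) {
  simulation_config(
    n_species = n_species,
    root_state = c(Y = 0, X = 0), bm_rates = c(Y = rate, X = rate),
    allometric_exponents = data.frame(y = "Y", x = "X", beta = beta, r2 = r2),
    tradeoff_correlations = NULL, seed = seed)
}

# Independent oracle for the Yule/ERM cherry expectation: simulate the
# growth process directly on tip "cherry partner" labels, never building a
# tree. Returns the Monte-Carlo mean cherry count for n tips.
erm_cherry_oracle <- function(n, n_reps = 2000L) {
  counts <- vapply(seq_len(n_reps), function(i) {
    partner <- c(2L, 1L) # tips 1 and 2 form a cherry
    while (length(partner) < n) {
      k <- length(partner)
      splt <- sample.int(k, 1L)
      if (partner[splt] > 0L) partner[partner[splt]] <- 0L
      partner[splt] <- k + 1L
      partner <- c(partner, splt)
    }
    sum(partner > 0L) / 2
  }, numeric(1))
  mean(counts)
}

# Cherry count of an ape tree: internal nodes whose two children are tips.
count_cherries <- function(tree) {
  ntip <- length(tree$tip.label)
  tab <- tapply(tree$edge[, 2] <= ntip, tree$edge[, 1], sum)
  sum(tab == 2)
}

# Independent recursive PIC oracle (plain R recursion on the edge matrix,
# no shared code with pic_contrasts' iterative postorder pass).
pic_oracle <- function(tree, trait) {
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  out <- new.env()
  out$contrasts <- list()
  rec <- function(node) {
    if (node <= ntip) {
      return(c(x = unname(trait[tree$tip.label[node]]), v = 0))
    }
    ei <- kids[[as.character(node)]]
    left <- rec(tree$edge[ei[1], 2])
    right <- rec(tree$edge[ei[2], 2])
    vl <- left["v"] + tree$edge.length[ei[1]]
    vr <- right["v"] + tree$edge.length[ei[2]]
    out$contrasts[[as.character(node)]] <-
      unname((left["x"] - right["x"]) / sqrt(vl + vr))
    c(x = unname((left["x"] / vl + right["x"] / vr) / (1 / vl + 1 / vr)),
      v = unname(vl * vr / (vl + vr)))
  }
  root <- ntip + 1L
  rec(root)
  nodes <- as.integer(names(out$contrasts))
  ord <- order(nodes)
  data.frame(node = nodes[ord],
             contrast = unlist(out$contrasts, use.names = FALSE)[ord])
}
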