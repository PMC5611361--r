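#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: either a simulation config or a
#' set of input file paths, the SMA pair list with hypothesized slopes, the
#' MFA trait grouping, and output options.
#'
#' @param simulation A [simulation_config()] (used when no `input` given).
#' @param input Optional named list of paths to existing inputs: `twig`,
#'   `vessel`, `gravimetric`, `bending` CSVs and optionally `tree` (newick).
#' @param sma_pairs Data frame `y`, `x`, `b0` ([default_sma_pairs()]).
#' @param trait_groups Named list for the MFA ([default_trait_groups()]).
#' @param outdir Optional output directory for CSVs, report and manifest.
#' @param seed Optional integer overriding `simulation$seed`.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = simulation_config(), input = NULL,
                            sma_pairs = default_sma_pairs(),
                            trait_groups = default_trait_groups(),
                            outdir = NULL, seed = NULL) {
  if (!is.null(input)) {
    need <- c("twig", "vessel", "gravimetric", "bending")
    miss <- setdiff(need, names(input))
    if (length(miss)) stop("invalid-argument: input paths missing: ",
                           paste(miss, collapse = ", "))
    gone <- unlist(input)[!file.exists(unlist(input))]
    if (length(gone)) stop("invalid-argument: input file(s) not found: ",
                           paste(gone, collapse = ", "))
  }
  stopifnot(all(c("y", "x") %in% names(sma_pairs)))
  structure(list(simulation = simulation, input = input,
                 sma_pairs = sma_pairs, trait_groups = trait_groups,
                 outdir = outdir, seed = seed),
            class = "pipeline_config")
}

.pipeline_stages <- c("simulate", "derive", "allometry", "pic", "mfa",
                      "varcomp")

#' Run the full comparative-analysis pipeline
#'
#' Orchestrates simulate (or load) -> derive -> aggregate -> analyze. Stages:
#' \describe{
#'   \item{simulate}{Generate the synthetic dataset (skipped when `input`
#'     paths are configured).}
#'   \item{derive}{Per-stem hydraulic, composition and bending traits; twig
#'     architecture traits; two-stage species means.}
#'   \item{allometry}{Log10 transform and SMA table with isometry tests.}
#'   \item{pic}{Independent contrasts and contrast correlations (skipped with
#'     a warning when no tree is available).}
#'   \item{mfa}{Multiple factor analysis over the stem/leaf groups, plus the
#'     cross-species Pearson matrix.}
#'   \item{varcomp}{Nested variance components per trait on log10 twig
#'     values.}
#' }
#' Deterministic given the seed; when `outdir` is set, CSV outputs, a
#' markdown report and a JSON run manifest (package version, seed, config
#' hash) are written. The manifest carries no timestamp so reruns are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @param skip Character vector of stage names to skip.
#' @return Object of class `twigscale_results`.
#' @export
run_pipeline <- function(config = pipeline_config(), skip = character()) {
  stopifnot(inherits(config, "pipeline_config"))
  bad <- setdiff(skip, .pipeline_stages)
  if (length(bad)) stop("invalid-argument: unknown stage(s): ",
                        paste(bad, collapse = ", "))
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  if (!is.null(config$seed)) config$simulation$seed <- as.integer(config$seed)
  results <- list(config = config)

  tree <- NULL
  if (!is.null(config$input)) {
    twig_table <- read.csv(config$input$twig)
    vessel_table <- read.csv(config$input$vessel)
    gravimetric_table <- read.csv(config$input$gravimetric)
    bending_table <- read.csv(config$input$bending)
    if (!is.null(config$input$tree)) tree <- parse_newick(config$input$tree)
  } else if (!("simulate" %in% skip)) {
    ds <- run("simulate", simulate_dataset(config$simulation))
    results$dataset <- ds
    twig_table <- ds$twig_table
    vessel_table <- ds$vessel_table
    gravimetric_table <- ds$gravimetric_table
    bending_table <- ds$bending_table
    tree <- ds$tree
  } else {
    stop("invalid-argument: nothing to analyse (simulation skipped, no input)")
  }

  if (!("derive" %in% skip)) {
    results$stem_traits <- run("derive", {
      hyd <- derive_stem_hydraulics(vessel_table)
      comp <- derive_stem_composition(gravimetric_table)
      bend <- derive_stem_bending(bending_table)
      Reduce(function(a, b) merge(a, b, by = "stem_id"),
             list(hyd, comp, bend[c("stem_id", "MOE")]))
    })
    results$twig_traits <- run("derive", {
      tw <- derive_twig_traits(twig_table)
      merge(tw, results$stem_traits, by = "stem_id")
    })
    results$species_means <- run("derive",
                                 aggregate_species_means(results$twig_traits))
  }

  traits_all <- names(results$species_means)
  logm <- run("derive", log10_prepare(results$species_means, traits_all))

  results$correlations <- run("derive", pearson_matrix(logm))

  if (!("allometry" %in% skip))
    results$sma <- run("allometry", sma_table(logm, config$sma_pairs))

  if (!("mfa" %in% skip))
    results$mfa <- run("mfa", mfa(logm, config$trait_groups))

  if (!("pic" %in% skip)) {
    if (is.null(tree)) {
      warning("pic stage skipped: no phylogeny available")
    } else {
      results$contrasts <- run("pic", pic_table(tree, logm))
      results$pic_correlations <- run("pic",
                                      pearson_matrix(results$contrasts))
    }
  }

  if (!("varcomp" %in% skip)) {
    results$varcomp <- run("varcomp", {
      tw <- results$twig_traits
      traits <- intersect(traits_all, names(tw))
      out <- lapply(traits, function(tr) {
        twl <- tw
        twl[[tr]] <- log10(twl[[tr]])
        vc <- nested_varcomp(twl, tr)
        data.frame(trait = tr, pct_species = vc$percent[["species"]],
                   pct_individual = vc$percent[["individual"]],
                   pct_twig = vc$percent[["twig"]])
      })
      do.call(rbind, out)
    })
  }

  results <- structure(results, class = "twigscale_results")
  if (!is.null(config$outdir)) write_outputs(results, config$outdir)
  results
}

# deterministic hash of the configuration (md5 of its canonical JSON);
# output location is not part of the scientific configuration
.config_hash <- function(config) {
  cfg <- config
  cfg$outdir <- NULL
  cfg$simulation$bm_rate_matrix <-
    as.data.frame(cfg$simulation$bm_rate_matrix)
  js <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(js), tmp)
  unname(tools::md5sum(tmp))
}

write_outputs <- function(results, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(x, f, rn = FALSE) write.csv(x, file.path(outdir, f),
                                               row.names = rn)
  if (!is.null(results$dataset)) {
    write_dataset(results$dataset, file.path(outdir, "inputs"))
  }
  if (!is.null(results$species_means))
    wcsv(cbind(species = rownames(results$species_means),
               results$species_means), "species_means.csv")
  if (!is.null(results$sma)) wcsv(results$sma, "sma_table.csv")
  if (!is.null(results$correlations)) {
    wcsv(results$correlations$r, "correlations_r.csv", rn = TRUE)
    wcsv(results$correlations$p, "correlations_p.csv", rn = TRUE)
  }
  if (!is.null(results$pic_correlations)) {
    wcsv(results$pic_correlations$r, "pic_correlations_r.csv", rn = TRUE)
    wcsv(results$pic_correlations$p, "pic_correlations_p.csv", rn = TRUE)
  }
  if (!is.null(results$contrasts)) {
    cs <- do.call(rbind, lapply(names(results$contrasts), function(tr) {
      data.frame(trait = tr, node = results$contrasts[[tr]]$node,
                 contrast = results$contrasts[[tr]]$contrast)
    }))
    wcsv(cs, "contrasts.csv")
  }
  if (!is.null(results$mfa)) {
    wcsv(results$mfa$loadings, "mfa_loadings.csv", rn = TRUE)
    wcsv(results$mfa$scores, "mfa_scores.csv", rn = TRUE)
    wcsv(data.frame(axis = seq_along(results$mfa$variance_percent),
                    variance_percent = results$mfa$variance_percent),
         "mfa_variance.csv")
  }
  if (!is.null(results$varcomp)) wcsv(results$varcomp, "varcomp.csv")
  manifest <- list(package = "twigscale",
                   version = as.character(packageVersion("twigscale")),
                   seed = results$config$seed %||% results$config$simulation$seed,
                   config_hash = .config_hash(results$config))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(write_report(results), file.path(outdir, "report.md"))
  invisible(outdir)
}

#' Human-readable analysis report
#'
#' Renders a markdown summary in the order allometry -> MFA -> trade-off
#' correlations -> size-trait correlations. All floating point values are
#' printed at 4 significant digits; CSV outputs keep full precision. Reruns
#' with the same seed produce a byte-identical report body.
#'
#' @param results A `twigscale_results` object.
#' @param file Optional path to write to.
#' @return Character vector of report lines, invisibly when writing to file.
#' @export
write_report <- function(results, file = NULL) {
  stopifnot(inherits(results, "twigscale_results"))
  fmt <- function(x) signif(x, 4)
  ln <- c("# Twig allometry analysis report", "")
  ln <- c(ln, sprintf("- seed: %s",
                      results$config$seed %||% results$config$simulation$seed),
          sprintf("- config hash: %s", .config_hash(results$config)), "")
  if (!is.null(results$sma)) {
    ln <- c(ln, "## Allometric scaling (SMA)", "",
            "| Y | X | n | R2 | slope | 95% CI | H0 | P | verdict |",
            "|---|---|---|----|-------|--------|----|---|---------|")
    for (i in seq_len(nrow(results$sma))) {
      r <- results$sma[i, ]
      verdict <- if (r$P < 0.05) "allometric" else "isometric"
      ln <- c(ln, sprintf("| %s | %s | %d | %s | %s | [%s, %s] | %g | %s | %s |",
                          r$Y, r$X, r$n, fmt(r$R2), fmt(r$slope),
                          fmt(r$ci_low), fmt(r$ci_high), r$b0, fmt(r$P),
                          verdict))
    }
    ln <- c(ln, "")
  }
  if (!is.null(results$mfa)) {
    vp <- results$mfa$variance_percent
    ln <- c(ln, "## Multiple factor analysis", "",
            sprintf("- axis 1: %s%% of variance; axis 2: %s%%",
                    fmt(vp[1]), fmt(vp[2])),
            sprintf("- group weights: %s",
                    paste(sprintf("%s = %s", names(results$mfa$group_weights),
                                  fmt(results$mfa$group_weights)),
                          collapse = ", ")), "")
  }
  corr_block <- function(r_mat, p_mat, pairs, title) {
    out <- c(sprintf("## %s", title), "",
             "| trait A | trait B | r | P |", "|---------|---------|---|---|")
    for (pr in pairs) {
      if (!all(pr %in% rownames(r_mat))) next
      out <- c(out, sprintf("| %s | %s | %s | %s |", pr[1], pr[2],
                            fmt(r_mat[pr[1], pr[2]]),
                            fmt(p_mat[pr[1], pr[2]])))
    }
    c(out, "")
  }
  if (!is.null(results$correlations)) {
    r_mat <- results$correlations$r
    p_mat <- results$correlations$p
    ln <- c(ln, corr_block(r_mat, p_mat,
                           list(c("Dh", "VD"), c("Dh", "VF"), c("Dh", "Ktheo"),
                                c("Ktheo", "WD"), c("WD", "MOE"),
                                c("Ktheo", "MOE")),
                           "Hydraulic efficiency vs mechanical strength"))
    ln <- c(ln, corr_block(r_mat, p_mat,
                           list(c("SA", "Dh"), c("SA", "VD"), c("SA", "VF"),
                                c("SA", "WD"), c("SA", "Ktheo"),
                                c("SA", "MOE"), c("Ktheo", "TLA"),
                                c("WD", "TLA"), c("Ktheo", "LI"),
                                c("WD", "LI")),
                           "Size vs hydraulic and mechanical traits"))
  }
  if (!is.null(results$pic_correlations)) {
    ln <- c(ln, corr_block(results$pic_correlations$r,
                           results$pic_correlations$p,
                           list(c("Dh", "VD"), c("Ktheo", "WD"),
                                c("SA", "Ktheo"), c("SA", "WD")),
                           "Phylogenetically independent contrasts"))
  }
  if (!is.null(results$varcomp)) {
    ln <- c(ln, "## Variance partition (log10 twig traits)", "",
            sprintf("- among-species share: median %s%%, range %s-%s%%",
                    fmt(stats::median(results$varcomp$pct_species)),
                    fmt(min(results$varcomp$pct_species)),
                    fmt(max(results$varcomp$pct_species))), "")
  }
  if (length(ln) <= 5L)
    ln <- c(ln, "(no analysis results; run metadata only)", "")
  if (!is.null(file)) {
    writeLines(ln, file)
    return(invisible(ln))
  }
  ln
}

#' @export
print.twigscale_results <- function(x, ...) {
  cat("twigscale pipeline results\n")
  for (nm in setdiff(names(x), "config"))
    cat("  -", nm, "\n")
  invisible(x)
}
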