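#' Derive twig architecture traits from raw measurements
#'
#' Adds the per-twig derived traits to a raw twig table: specific leaf area
#' `SLA = TLA / LeM` (converted to m^2 kg^-1), individual lamina area
#' `ILA = TLA / n`, individual lamina mass `ILM = LeM / n`, individual petiole
#' mass `IPM = total petiole mass / n`, and mass-based leafing intensity
#' `LI = n / SM` (leaves per g stem dry mass), with `n` the leaf count.
#' Raw columns are also exposed under their trait codes (`SA`, `SM`, `TLA`,
#' `LeM`, `PA`).
#'
#' @param twigs Data frame with columns `species`, `individual`, `twig`,
#'   `stem_area_mm2`, `stem_mass_g`, `leaf_count`, `total_lamina_area_cm2`,
#'   `total_lamina_mass_g`, `total_petiole_mass_g`, `petiole_area_mm2`.
#' @return The input with appended trait-code columns.
#' @examples
#' tw <- data.frame(species = "sp01", individual = 1, twig = 1,
#'                  stem_area_mm2 = 8, stem_mass_g = 2, leaf_count = 10,
#'                  total_lamina_area_cm2 = 300, total_lamina_mass_g = 2,
#'                  total_petiole_mass_g = 0.5, petiole_area_mm2 = 3)
#' derive_twig_traits(tw)[, c("SLA", "ILA", "LI")]
#' @export
derive_twig_traits <- function(twigs) {
  need <- c("species", "individual", "twig", "stem_area_mm2", "stem_mass_g",
            "leaf_count", "total_lamina_area_cm2", "total_lamina_mass_g",
            "total_petiole_mass_g", "petiole_area_mm2")
  miss <- setdiff(need, names(twigs))
  if (length(miss)) stop("schema error: twig table missing column(s): ",
                         paste(miss, collapse = ", "))
  num <- twigs[, need[-(1:3)]]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) <= 0))
    stop("invalid-argument: all twig measurements must be positive and finite")
  if (any(twigs$leaf_count < 1))
    stop("invalid-argument: leaf count must be >= 1")

  n <- twigs$leaf_count
  twigs$SA  <- twigs$stem_area_mm2
  twigs$SM  <- twigs$stem_mass_g
  twigs$TLA <- twigs$total_lamina_area_cm2
  twigs$LeM <- twigs$total_lamina_mass_g
  twigs$PA  <- twigs$petiole_area_mm2
  # cm^2 / g -> m^2 / kg
  twigs$SLA <- (twigs$TLA * .units$cm2_to_m2) / (twigs$LeM * .units$g_to_kg)
  twigs$ILA <- twigs$TLA / n
  twigs$ILM <- twigs$LeM / n
  twigs$IPM <- twigs$total_petiole_mass_g / n
  twigs$LI  <- n / twigs$SM
  twigs
}

#' Two-stage aggregation of twig traits to species means
#'
#' Averages trait values arithmetically per individual first and then per
#' species, so individuals (not twigs) are the replicates. This differs from a
#' pooled twig mean whenever twig counts are unbalanced. Species with an
#' all-missing trait get `NA` for that trait with a warning.
#'
#' @param twigs Twig table including derived trait columns (see
#'   [derive_twig_traits()]).
#' @param traits Character vector of trait columns to aggregate; defaults to
#'   every trait code present.
#' @return Data frame with one row per species (rownames = species) and one
#'   column per trait.
#' @export
aggregate_species_means <- function(twigs, traits = NULL) {
  codes <- c("SA", "SM", "Dh", "VD", "VF", "Ktheo", "WD", "SWC", "MOE", "PA",
             "IPM", "TLA", "ILA", "LeM", "ILM", "SLA", "LI", "LT", "UET",
             "PT", "SP", "LET", "SS", "SD")
  if (is.null(traits)) traits <- intersect(codes, names(twigs))
  miss <- setdiff(traits, names(twigs))
  if (length(miss)) stop("schema error: trait column(s) absent: ",
                         paste(miss, collapse = ", "))
  if (!all(c("species", "individual") %in% names(twigs)))
    stop("schema error: twig table needs 'species' and 'individual' columns")

  ind <- aggregate(twigs[traits],
                   by = list(species = twigs$species,
                             individual = twigs$individual),
                   FUN = mean, na.rm = TRUE)
  sp <- aggregate(ind[traits], by = list(species = ind$species),
                  FUN = mean, na.rm = TRUE)
  out <- sp[traits]
  out[] <- lapply(out, function(v) ifelse(is.nan(v), NA_real_, v))
  rownames(out) <- sp$species
  all_na <- vapply(traits, function(tr) any(is.na(out[[tr]])), logical(1))
  if (any(all_na))
    warning("species with missing mean for trait(s): ",
            paste(traits[all_na], collapse = ", "))
  out
}
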