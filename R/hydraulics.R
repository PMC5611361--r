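#' Physical constants for hydraulic calculations
#'
#' Density and dynamic viscosity of water at 20 degrees C, the reference
#' conditions used for theoretical conductivity. Overridable for sensitivity
#' analyses.
#'
#' @param rho_water Water density, kg m^-3.
#' @param mu_water Water viscosity, MPa s.
#' @return A list of class `physical_constants`.
#' @examples
#' physical_constants()
#' @export
physical_constants <- function(rho_water = 998.2, mu_water = 1.002e-9) {
  stopifnot(is.numeric(rho_water), rho_water > 0,
            is.numeric(mu_water), mu_water > 0)
  structure(list(rho_water = rho_water, mu_water = mu_water),
            class = "physical_constants")
}

#' Poiseuille-equivalent diameter of an elliptical vessel
#'
#' Converts the semi-axes of an elliptical vessel lumen into the diameter of
#' the circular conduit with identical laminar (Hagen-Poiseuille) flow
#' resistance: `D = (32 (ab)^3 / (a^2 + b^2))^(1/4)`. In the circular limit
#' `a = b = r` this returns `2r`, so inputs are interpreted as SEMI-axes; pass
#' `full_axes = TRUE` if your image-analysis export reports full major/minor
#' axis lengths instead.
#'
#' @param a,b Semi-major and semi-minor axis, um. Vectorized; `a >= b > 0`.
#' @param full_axes If `TRUE`, `a` and `b` are full axis lengths and are halved
#'   on ingest.
#' @return Equivalent diameter(s), um.
#' @examples
#' ellipse_equivalent_diameter(7.5, 7.5) # circular vessel of radius 7.5 -> 15
#' @export
ellipse_equivalent_diameter <- function(a, b, full_axes = FALSE) {
  if (length(a) != length(b)) stop("invalid-argument: 'a' and 'b' must have equal length")
  if (isTRUE(full_axes)) {
    a <- a / 2
    b <- b / 2
  }
  if (any(!is.finite(a)) || any(!is.finite(b)) || any(a <= 0) || any(b <= 0))
    stop("invalid-argument: vessel axes must be finite and positive")
  if (any(a < b))
    stop("invalid-argument: semi-major axis 'a' must be >= semi-minor axis 'b'")
  (32 * (a * b)^3 / (a^2 + b^2))^0.25
}

#' Hydraulically weighted vessel diameter
#'
#' Fourth-power mean of vessel diameters, `D_h = (mean(D^4))^(1/4)`, which
#' weights each vessel by its contribution to Poiseuille flow.
#'
#' @param d Vector of vessel diameters, um; nonempty, all positive.
#' @return `D_h`, um.
#' @examples
#' hydraulic_weighted_diameter(c(10, 20)) # ~17.08
#' @export
hydraulic_weighted_diameter <- function(d) {
  if (length(d) < 1L) stop("invalid-argument: need at least one vessel diameter")
  if (any(!is.finite(d)) || any(d <= 0))
    stop("invalid-argument: vessel diameters must be finite and positive")
  mean(d^4)^0.25
}

#' Construct and validate a per-stem vessel measurement set
#'
#' @param stem_id Stem identifier (scalar).
#' @param a_um,b_um Semi-major and semi-minor vessel axes, um.
#' @param analyzed_xylem_area_mm2 Area of the xylem window in which the vessels
#'   were measured, mm^2.
#' @param sapwood_area_mm2 Optional whole cross-section sapwood area, mm^2.
#' @param full_axes Are `a_um`/`b_um` full axis lengths? See
#'   [ellipse_equivalent_diameter()].
#' @return A list of class `vessel_set`.
#' @export
vessel_set <- function(stem_id, a_um, b_um, analyzed_xylem_area_mm2,
                       sapwood_area_mm2 = NA_real_, full_axes = FALSE) {
  if (isTRUE(full_axes)) {
    a_um <- a_um / 2
    b_um <- b_um / 2
  }
  if (length(a_um) < 1L) stop("invalid-argument: vessel set needs >= 1 vessel")
  if (any(a_um < b_um) || any(b_um <= 0))
    stop("invalid-argument: require a >= b > 0 for every vessel")
  if (!is.finite(analyzed_xylem_area_mm2) || analyzed_xylem_area_mm2 <= 0)
    stop("invalid-argument: analyzed xylem area must be positive")
  structure(list(stem_id = stem_id, a_um = a_um, b_um = b_um,
                 analyzed_xylem_area_mm2 = analyzed_xylem_area_mm2,
                 sapwood_area_mm2 = sapwood_area_mm2),
            class = "vessel_set")
}

#' Vessel density and vessel lumen fraction
#'
#' `VD` is the number of vessels per unit analyzed xylem area (mm^-2); `VF` is
#' the mean elliptical lumen area (`pi a b`) times `VD`, returned as a fraction
#' of the cross-section. A `VF >= 1` is physically impossible and triggers a
#' data-consistency warning.
#'
#' @param vessels A [vessel_set()].
#' @return List with elements `VD` (mm^-2) and `VF` (fraction).
#' @export
vessel_stats <- function(vessels) {
  stopifnot(inherits(vessels, "vessel_set"))
  area <- vessels$analyzed_xylem_area_mm2
  if (area <= 0) stop("invalid-argument: zero analyzed xylem area")
  vd <- length(vessels$a_um) / area
  lumen_mm2 <- pi * vessels$a_um * vessels$b_um * .units$um2_to_mm2
  vf <- mean(lumen_mm2) * vd
  if (vf >= 1)
    warning("data-consistency: vessel fraction >= 1; check axis convention and areas")
  list(VD = vd, VF = vf)
}

#' Theoretical specific hydraulic conductivity (Hagen-Poiseuille)
#'
#' `K_theo = pi * rho / (128 * mu * A_s) * sum(D^4)` with diameters converted
#' to meters and the normalizing xylem area `A_s` to m^2. Units follow from
#' `mu` in MPa s: kg m^-1 MPa^-1 s^-1. `K_theo` ignores wall and end
#' resistances and so upper-bounds measurable conductivity; it is used as a
#' porosity-style index of hydraulic efficiency.
#'
#' @param d_um Vessel diameters, um (e.g. from
#'   [ellipse_equivalent_diameter()]).
#' @param As_mm2 Cross-sectional xylem area over which the vessels were
#'   counted, mm^2 (the sapwood area if `d_um` covers the whole section, or
#'   the analyzed window area for a sub-sampled section).
#' @param constants A [physical_constants()] object.
#' @return `K_theo`, kg m^-1 MPa^-1 s^-1; 0 (with a warning) for an empty
#'   vessel list.
#' @examples
#' theoretical_conductivity(rep(20, 100), 1) # ~0.391
#' @export
theoretical_conductivity <- function(d_um, As_mm2, constants = physical_constants()) {
  stopifnot(inherits(constants, "physical_constants"))
  if (!is.finite(As_mm2) || As_mm2 <= 0)
    stop("invalid-argument: xylem area must be positive")
  if (length(d_um) == 0L) {
    warning("no vessels supplied; K_theo = 0")
    return(0)
  }
  if (any(!is.finite(d_um)) || any(d_um <= 0))
    stop("invalid-argument: vessel diameters must be finite and positive")
  d_m <- d_um * .units$um_to_m
  As_m2 <- As_mm2 * .units$mm2_to_m2
  pi * constants$rho_water / (128 * constants$mu_water * As_m2) * sum(d_m^4)
}

#' Derive per-stem hydraulic traits from a long-format vessel table
#'
#' Groups a vessel table by `stem_id` and computes, per stem, the equivalent
#' diameters, hydraulically weighted diameter `Dh`, vessel density `VD`,
#' vessel fraction `VF` and theoretical conductivity `Ktheo`. `Ktheo` is
#' normalized by the analyzed window area: vessel density per xylem area in
#' the window is taken as representative of the sapwood, which makes the
#' window-normalized sum equivalent to the sapwood-normalized sum over all
#' sapwood vessels.
#'
#' @param vessel_table Data frame with columns `stem_id`, `a_um`, `b_um`,
#'   `analyzed_xylem_area_mm2` (constant within stem).
#' @param constants A [physical_constants()] object.
#' @param full_axes Passed to [ellipse_equivalent_diameter()].
#' @return Data frame keyed by `stem_id` with columns `n_vessels`, `Dh`, `VD`,
#'   `VF`, `Ktheo`.
#' @export
derive_stem_hydraulics <- function(vessel_table, constants = physical_constants(),
                                   full_axes = FALSE) {
  need <- c("stem_id", "a_um", "b_um", "analyzed_xylem_area_mm2")
  miss <- setdiff(need, names(vessel_table))
  if (length(miss)) stop("schema error: vessel table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(vessel_table, vessel_table$stem_id), function(vt) {
    vs <- vessel_set(vt$stem_id[1L], vt$a_um, vt$b_um,
                     vt$analyzed_xylem_area_mm2[1L], full_axes = full_axes)
    d <- ellipse_equivalent_diameter(vs$a_um, vs$b_um)
    st <- vessel_stats(vs)
    data.frame(stem_id = vt$stem_id[1L], n_vessels = length(d),
               Dh = hydraulic_weighted_diameter(d), VD = st$VD, VF = st$VF,
               Ktheo = theoretical_conductivity(d, vs$analyzed_xylem_area_mm2,
                                                constants))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
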