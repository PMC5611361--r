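#' Wood density and saturated water content from gravimetric measurements
#'
#' `WD = DW / fresh_volume` (g cm^-3) and
#' `SWC = (FW - DW) / (SW - DW) * 100` (%), where `FW`, `SW` and `DW` are the
#' fresh, saturated and oven-dry masses of a debarked, de-pithed stem segment.
#' `SWC` expresses field water content relative to the saturable pore space.
#'
#' @param FW,SW,DW Fresh, saturated and dry mass, g. Vectorized.
#' @param fresh_volume Fresh volume by water displacement, cm^3.
#' @return Data frame with columns `WD` (g cm^-3) and `SWC` (%).
#' @examples
#' stem_composition(FW = 2, SW = 2.5, DW = 1, fresh_volume = 1.2)
#' @export
stem_composition <- function(FW, SW, DW, fresh_volume) {
  n <- length(FW)
  stopifnot(length(SW) == n, length(DW) == n, length(fresh_volume) == n)
  if (any(!is.finite(c(FW, SW, DW, fresh_volume))))
    stop("invalid-argument: gravimetric inputs must be finite")
  if (any(DW <= 0) || any(fresh_volume <= 0))
    stop("invalid-argument: dry mass and fresh volume must be positive")
  if (any(SW < FW) || any(FW < DW))
    stop("invalid-argument: require SW >= FW >= DW")
  if (any(SW == DW))
    stop("division-by-zero: SW equals DW (no saturable pore space) for record(s) ",
         paste(which(SW == DW), collapse = ", "))
  data.frame(WD = DW / fresh_volume, SWC = (FW - DW) / (SW - DW) * 100)
}

#' Flexural stiffness and structural Young's modulus from three-point bending
#'
#' A stem segment of span `L` loaded at midspan deflects by
#' `delta = F L^3 / (48 EI)`. The least-squares slope `s` of deflection on
#' load therefore gives `EI = L^3 / (48 s)`; the structural modulus is
#' `MOE = EI / I` with the solid-circle second moment of area
#' `I = pi d^4 / 64` (pith assumed removed). Span-to-diameter ratios below 25
#' risk shear contamination and trigger a warning; below 20 the test is
#' rejected.
#'
#' @param span_L Support span, mm.
#' @param stem_diameter_d Stem diameter, mm.
#' @param loads Applied midspan loads, N; strictly increasing, >= 3 values.
#' @param deflections Midspan deflections, mm; same length as `loads`.
#' @param r2_warn,r2_reject Linearity thresholds on the deflection-load fit.
#' @return List of class `bending_fit` with `EI` (N mm^2), `MOE` (MPa),
#'   `slope` (mm N^-1) and `r_squared`.
#' @examples
#' bending_moe(100, 4, loads = 1:4, deflections = 0.5 * (1:4))
#' @export
bending_moe <- function(span_L, stem_diameter_d, loads, deflections,
                        r2_warn = 0.95, r2_reject = 0.8) {
  stopifnot(is.numeric(span_L), span_L > 0,
            is.numeric(stem_diameter_d), stem_diameter_d > 0)
  if (length(loads) < 3L || length(deflections) != length(loads))
    stop("invalid-argument: need >= 3 matched load-deflection pairs")
  if (any(diff(loads) <= 0))
    stop("invalid-argument: loads must be strictly increasing")
  ratio <- span_L / stem_diameter_d
  if (ratio < 20)
    stop("invalid-argument: span-to-diameter ratio ", round(ratio, 1),
         " < 20; shear would contaminate the bending estimate")
  if (ratio < 25)
    warning("span-to-diameter ratio ", round(ratio, 1),
            " below the recommended 25:1")
  fit <- lm(deflections ~ loads)
  s <- unname(coef(fit)[2L])
  r2 <- cor(loads, deflections)^2
  if (!is.finite(s) || s <= 0)
    stop("invalid-argument: deflection must increase with load")
  if (r2 < r2_reject)
    stop("rejected: deflection-load relation nonlinear (r^2 = ",
         round(r2, 3), " < ", r2_reject, ")")
  if (r2 < r2_warn)
    warning("deflection-load linearity weak (r^2 = ", round(r2, 3), ")")
  EI <- span_L^3 / (48 * s)
  I <- pi * stem_diameter_d^4 / 64
  structure(list(EI = EI, MOE = EI / I, slope = s, r_squared = r2,
                 span_L = span_L, stem_diameter_d = stem_diameter_d),
            class = "bending_fit")
}

#' @export
print.bending_fit <- function(x, ...) {
  cat("Three-point bending fit\n")
  cat(sprintf("  span %.4g mm, diameter %.4g mm (ratio %.3g)\n",
              x$span_L, x$stem_diameter_d, x$span_L / x$stem_diameter_d))
  cat(sprintf("  EI  = %.4g N mm^2\n  MOE = %.4g MPa (r^2 = %.4f)\n",
              x$EI, x$MOE, x$r_squared))
  invisible(x)
}

#' Derive per-stem composition traits from a gravimetric table
#'
#' @param gravimetric_table Data frame with columns `stem_id`, `fw_g`, `sw_g`,
#'   `dw_g`, `fresh_volume_cm3`.
#' @return Data frame keyed by `stem_id` with `WD` (g cm^-3) and `SWC` (%).
#' @export
derive_stem_composition <- function(gravimetric_table) {
  need <- c("stem_id", "fw_g", "sw_g", "dw_g", "fresh_volume_cm3")
  miss <- setdiff(need, names(gravimetric_table))
  if (length(miss)) stop("schema error: gravimetric table missing column(s): ",
                         paste(miss, collapse = ", "))
  cbind(stem_id = gravimetric_table$stem_id,
        stem_composition(gravimetric_table$fw_g, gravimetric_table$sw_g,
                         gravimetric_table$dw_g,
                         gravimetric_table$fresh_volume_cm3))
}

#' Derive per-stem bending traits from a long-format bending table
#'
#' @param bending_table Data frame with columns `stem_id`, `span_mm`,
#'   `diameter_mm`, `load_n`, `deflection_mm`; one row per load step.
#' @return Data frame keyed by `stem_id` with `EI` (N mm^2), `MOE` (MPa) and
#'   the linearity `r_squared`.
#' @export
derive_stem_bending <- function(bending_table) {
  need <- c("stem_id", "span_mm", "diameter_mm", "load_n", "deflection_mm")
  miss <- setdiff(need, names(bending_table))
  if (length(miss)) stop("schema error: bending table missing column(s): ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(bending_table, bending_table$stem_id), function(bt) {
    ord <- order(bt$load_n)
    fit <- bending_moe(bt$span_mm[1L], bt$diameter_mm[1L],
                       bt$load_n[ord], bt$deflection_mm[ord])
    data.frame(stem_id = bt$stem_id[1L], EI = fit$EI, MOE = fit$MOE,
               r_squared = fit$r_squared)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
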