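#' Percent constriction of a pressurized artery
#'
#' `100 * (d_before - d_after) / d_before`, where `d_before` is the arterial
#' diameter before a treatment and `d_after` the diameter after it. A
#' negative value means the vessel dilated; it is returned as-is with a
#' `net_dilation` attribute set.
#'
#' @param d_before,d_after diameters (same units, e.g. um); `d_before > 0`.
#' @return percent constriction (numeric, `net_dilation` attribute flags
#'   negative results).
#' @export
#' @examples
#' percent_constriction(100, 80)  # 20
percent_constriction <- function(d_before, d_after) {
  if (any(!is.finite(d_before)) || any(d_before <= 0))
    stop("d_before must be positive", call. = FALSE)
  out <- 100 * (d_before - d_after) / d_before
  attr(out, "net_dilation") <- out < 0
  out
}

#' Percent dilation relative to the passive diameter
#'
#' `100 * (d_dilated - d_basal) / (d_ca_free - d_basal)`: dilation of a
#' pre-constricted vessel expressed as a fraction of its maximum passive
#' dilation, measured in Ca2+-free solution at the same pressure. 0 when
#' the vessel stays at its basal (pre-constricted) diameter, 100 at full
#' passive dilation.
#'
#' @param d_basal pre-constricted (basal) diameter.
#' @param d_dilated diameter after the dilator.
#' @param d_ca_free maximum passive diameter in Ca2+-free solution.
#' @return percent dilation.
#' @export
#' @examples
#' percent_dilation(60, 90, 100)  # 75
percent_dilation <- function(d_basal, d_dilated, d_ca_free) {
  if (any(d_ca_free == d_basal))
    stop("degenerate denominator: d_ca_free equals d_basal", call. = FALSE)
  if (any(d_ca_free < d_basal))
    warning("passive (Ca2+-free) diameter below basal diameter")
  100 * (d_dilated - d_basal) / (d_ca_free - d_basal)
}

#' Percentage myogenic tone
#'
#' Pressure-induced active constriction relative to the passive diameter:
#' `100 * (d_ca_free - d_active) / d_ca_free`, where `d_ca_free` is the
#' maximum passive diameter in Ca2+-free solution at the same intraluminal
#' pressure (15 mm Hg for fourth-order pulmonary arteries) and `d_active`
#' the diameter with tone intact. The passive-diameter denominator is a
#' package choice (see the methods vignette); pass
#' `reference = "active"` to normalise by `d_active` instead.
#'
#' @param d_active active diameter.
#' @param d_ca_free passive (Ca2+-free) diameter, > 0.
#' @param reference denominator: `"passive"` (default) or `"active"`.
#' @return percent myogenic tone.
#' @export
#' @examples
#' myogenic_tone(85, 100)  # 15
myogenic_tone <- function(d_active, d_ca_free,
                          reference = c("passive", "active")) {
  reference <- match.arg(reference)
  if (any(!is.finite(d_ca_free)) || any(d_ca_free <= 0))
    stop("d_ca_free must be positive", call. = FALSE)
  denom <- if (reference == "passive") d_ca_free else d_active
  if (reference == "active" && any(d_active <= 0))
    stop("d_active must be positive with reference = 'active'", call. = FALSE)
  100 * (d_ca_free - d_active) / denom
}

#' Flow record for wall shear stress
#'
#' Holds viscosity, volumetric flow and internal radius with explicit unit
#' hints; values are converted to CGS (poise, cm^3/s, cm) on construction.
#' Missing unit hints are an error — the constructor refuses to guess.
#'
#' @param viscosity dynamic viscosity.
#' @param flow volumetric flow rate.
#' @param radius internal vessel radius.
#' @param units named character vector with entries `viscosity`
#'   (`"poise"` or `"cP"`), `flow` (`"cm3_s"` or `"uL_min"`) and `radius`
#'   (`"cm"` or `"um"`).
#' @return an object of class `flow_record` (CGS units).
#' @export
#' @examples
#' flow_record(0.007, 2, 25,
#'             units = c(viscosity = "poise", flow = "uL_min", radius = "um"))
flow_record <- function(viscosity, flow, radius, units) {
  req <- c("viscosity", "flow", "radius")
  if (missing(units) || !all(req %in% names(units)))
    stop("unit hints required for viscosity, flow and radius", call. = FALSE)
  mu <- switch(units[["viscosity"]],
               poise = viscosity, cP = viscosity / 100,
               stop("unknown viscosity unit: ", units[["viscosity"]], call. = FALSE))
  q <- switch(units[["flow"]],
              cm3_s = flow, uL_min = flow * 1e-3 / 60,
              stop("unknown flow unit: ", units[["flow"]], call. = FALSE))
  r <- switch(units[["radius"]],
              cm = radius, um = radius * 1e-4,
              stop("unknown radius unit: ", units[["radius"]], call. = FALSE))
  if (any(!is.finite(c(mu, q, r))) || any(c(mu, q, r) <= 0))
    stop("viscosity, flow and radius must be positive", call. = FALSE)
  structure(list(viscosity_poise = mu, flow_cm3_s = q, radius_cm = r,
                 input_units = units),
            class = "flow_record")
}

#' Poiseuille wall shear stress
#'
#' `tau = 4 * mu * Qdot / (pi * r^3)` in dyn/cm^2, for dynamic viscosity
#' `mu` (poise), volumetric flow `Qdot` (cm^3/s) and internal radius `r`
#' (cm). Physiological luminal shear in small pulmonary arteries spans
#' roughly 4-14 dyn/cm^2.
#'
#' @param flow a [flow_record()].
#' @return wall shear stress, dyn/cm^2.
#' @export
#' @examples
#' shear_stress(flow_record(1, pi, 1,
#'   units = c(viscosity = "poise", flow = "cm3_s", radius = "cm")))  # 4
shear_stress <- function(flow) {
  stopifnot(inherits(flow, "flow_record"))
  4 * flow$viscosity_poise * flow$flow_cm3_s / (pi * flow$radius_cm^3)
}

#' Vessel-reactivity table
#'
#' Vectorised convenience over a data.frame of per-artery summary diameters
#' (one row per artery x condition). Recognised columns: `d_before`,
#' `d_after` (percent constriction); `d_basal`, `d_dilated`, `d_ca_free`
#' (percent dilation); `d_active`, `d_ca_free` (myogenic tone);
#' `viscosity_poise`, `flow_cm3_s`, `radius_cm` (shear stress, CGS);
#' optional `ns309_ok` logical viability flag (rows failing the NS309 full
#' dilation check are marked excluded, not dropped).
#'
#' @param df input data.frame.
#' @return the data.frame with computed columns appended (`pct_constriction`,
#'   `pct_dilation`, `myogenic_tone_pct`, `shear_dyn_cm2`, `excluded`).
#' @export
vessel_table <- function(df) {
  stopifnot(is.data.frame(df))
  out <- df
  if (all(c("d_before", "d_after") %in% names(df)))
    out$pct_constriction <- as.numeric(percent_constriction(df$d_before, df$d_after))
  if (all(c("d_basal", "d_dilated", "d_ca_free") %in% names(df)))
    out$pct_dilation <- percent_dilation(df$d_basal, df$d_dilated, df$d_ca_free)
  if (all(c("d_active", "d_ca_free") %in% names(df)))
    out$myogenic_tone_pct <- myogenic_tone(df$d_active, df$d_ca_free)
  if (all(c("viscosity_poise", "flow_cm3_s", "radius_cm") %in% names(df)))
    out$shear_dyn_cm2 <- 4 * df$viscosity_poise * df$flow_cm3_s /
      (pi * df$radius_cm^3)
  out$excluded <- if ("ns309_ok" %in% names(df)) !df$ns309_ok else FALSE
  out
}
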