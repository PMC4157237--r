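# Incubation flux computation: paired O2 concentrations -> blank-corrected
# net production, respiration and gross production per m^2 of 3D specimen
# surface per hour.

# concentration change -> mmol L^-1. Optode readings are mg L^-1 by default;
# a units switch accepts umol L^-1 input directly.
conc_to_mmol <- function(delta, units) {
  switch(units,
         mg_l = delta / O2_MOLAR_MASS,
         umol_l = delta / 1000,
         stop_config("unknown concentration units '%s' (use 'mg_l' or 'umol_l')", units))
}

#' Mean blank O2 drift rate for one site/season/phase
#'
#' Blank (seawater-only) incubations measure the O2 signal of the water
#' column itself; their mean rate is subtracted from specimen rates. Several
#' blanks matching the key are averaged.
#'
#' @param blanks data.frame of blank records (columns site, season, phase,
#'   o2_start_mg_l, o2_end_mg_l, duration_h; the concentration columns are
#'   interpreted per \code{units}).
#' @param site,season,phase key to match.
#' @param units input concentration units, \code{"mg_l"} (default) or
#'   \code{"umol_l"}.
#' @return Blank rate in mmol O2 L^-1 h^-1 (scalar).
#' @export
blank_rate <- function(blanks, site, season, phase, units = "mg_l") {
  sel <- blanks[blanks$site == site & blanks$season == season & blanks$phase == phase, ]
  if (nrow(sel) == 0) {
    stop_config("no blank incubation for (site=%s, season=%s, phase=%s); refusing to assume zero",
                site, season, phase)
  }
  assert_positive(sel$duration_h, "duration_h")
  rates <- conc_to_mmol(sel$o2_end_mg_l - sel$o2_start_mg_l, units) / sel$duration_h
  mean(rates)
}

#' Blank-corrected specimen O2 flux
#'
#' Computes the signed flux of one incubation:
#' \deqn{flux = ((\Delta C / \Delta t - blank) \cdot V) / (A_{2D} \cdot s)}
#' with the concentration change converted to mmol L^-1 (molar mass of O2
#' 31.998 g mol^-1 for mg L^-1 input), volume in litres and the planar area
#' (cm^2) scaled by the group's 2D-to-3D conversion factor and converted to
#' m^2. The result is per m^2 of 3D specimen surface per hour; light-phase
#' fluxes are net production, dark-phase fluxes are negative when the
#' specimen respires.
#'
#' All arguments are vectorized.
#'
#' @param o2_start,o2_end concentrations before/after incubation (units per
#'   \code{units}).
#' @param duration_h incubation duration (hours, > 0).
#' @param volume_l container volume (litres, > 0).
#' @param area2d_cm2 planar specimen area (cm^2, > 0).
#' @param blank blank rate in mmol L^-1 h^-1 (see \code{\link{blank_rate}}).
#' @param s_factor 2D-to-3D surface conversion factor (>= 1).
#' @param units concentration units, \code{"mg_l"} or \code{"umol_l"}.
#' @return Signed flux in mmol O2 m^-2 (3D specimen area) h^-1.
#' @export
#' @examples
#' # +0.48 mg/L over 1 h in 0.6 L on 30 cm^2 of 3D surface:
#' specimen_flux(6.5, 6.98, 1, 0.6, 30, blank = 0, s_factor = 1)
specimen_flux <- function(o2_start, o2_end, duration_h, volume_l, area2d_cm2,
                          blank, s_factor, units = "mg_l") {
  assert_positive(duration_h, "duration_h")
  assert_positive(volume_l, "volume_l")
  assert_positive(area2d_cm2, "area2d_cm2")
  if (any(s_factor < 1)) stop_config("s_factor must be >= 1")
  rate <- conc_to_mmol(o2_end - o2_start, units) / duration_h - blank
  area3d_m2 <- area2d_cm2 * 1e-4 * s_factor
  rate * volume_l / area3d_m2
}

#' Assemble net production, respiration and gross production
#'
#' Pairs a specimen's light-phase and dark-phase fluxes: net production (P_n)
#' is the light flux; respiration (R) is the dark flux negated, stored as a
#' positive magnitude; gross production is P_g = P_n + R. A dark flux that is
#' positive beyond \code{tol} (apparent O2 production in darkness) is a
#' degenerate measurement: a warning is issued and respiration is clamped at
#' zero, preserving the P_g identity.
#'
#' @param light_flux,dark_flux signed fluxes from
#'   \code{\link{specimen_flux}} (vectorized, element-wise pairing).
#' @param tol tolerance on positive dark flux before warning/clamping.
#' @return data.frame with columns p_n, resp, p_g.
#' @export
assemble_pn_r_pg <- function(light_flux, dark_flux, tol = 1e-8) {
  if (length(light_flux) != length(dark_flux)) {
    stop_config("light and dark flux vectors must have equal length")
  }
  resp <- -dark_flux
  bad <- resp < -tol
  if (any(bad)) {
    warning(sprintf("%d dark incubation(s) show net O2 production; respiration clamped to 0", sum(bad)))
  }
  resp[resp < 0] <- 0
  data.frame(p_n = light_flux, resp = resp, p_g = light_flux + resp)
}

#' Convert illuminance to photosynthetically active radiation
#'
#' PAR (umol photons m^-2 s^-1, 400--700 nm) approximated as a fixed multiple
#' of illuminance in lx. The default constant 0.0185 is a common daylight
#' approximation; it is exposed because logger deployments differ.
#'
#' @param light_lx illuminance in lx (>= 0, vectorized).
#' @param k conversion constant (PAR per lx).
#' @return PAR in umol photons m^-2 s^-1.
#' @export
lux_to_par <- function(light_lx, k = 0.0185) {
  assert_nonneg(light_lx, "light_lx")
  k * light_lx
}

#' Compute all specimen fluxes from incubation and blank tables
#'
#' The flux stage of the pipeline: per incubation record, subtracts the mean
#' blank rate of its (site, season, phase), normalizes by 3D specimen area
#' (planar area times the group's conversion-factor mean) and pairs each
#' specimen's light and dark incubations into P_n, R, P_g. Specimens lacking
#' either phase are dropped with a warning.
#'
#' @param incubations data.frame with columns sample_id, group, site, season,
#'   phase, o2_start_mg_l, o2_end_mg_l, duration_h, volume_l, area2d_cm2.
#' @param blanks blank records (see \code{\link{blank_rate}}).
#' @param conversion_factors data.frame with columns group and s (or mean):
#'   the per-group 2D-to-3D conversion factor applied for area normalization.
#' @param units concentration units of both tables.
#' @return data.frame with columns sample_id, group, site, season, p_n, resp,
#'   p_g, light_flux, dark_flux (the signed per-phase fluxes are retained for
#'   validation).
#' @export
compute_fluxes <- function(incubations, blanks, conversion_factors, units = "mg_l") {
  s_col <- if ("s" %in% names(conversion_factors)) "s" else "mean"
  s_map <- stats::setNames(conversion_factors[[s_col]], conversion_factors$group)
  missing_g <- setdiff(unique(incubations$group), names(s_map))
  if (length(missing_g) > 0) {
    stop_config("no conversion factor for group(s): %s", paste(missing_g, collapse = ", "))
  }
  keys <- unique(incubations[, c("site", "season", "phase")])
  bmap <- stats::setNames(
    vapply(seq_len(nrow(keys)), function(i) {
      blank_rate(blanks, keys$site[i], keys$season[i], keys$phase[i], units)
    }, numeric(1)),
    paste(keys$site, keys$season, keys$phase)
  )
  flux <- specimen_flux(
    incubations$o2_start_mg_l, incubations$o2_end_mg_l,
    incubations$duration_h, incubations$volume_l, incubations$area2d_cm2,
    blank = unname(bmap[paste(incubations$site, incubations$season, incubations$phase)]),
    s_factor = unname(s_map[incubations$group]),
    units = units
  )
  light <- incubations[incubations$phase == "light", c("sample_id", "group", "site", "season")]
  light$light_flux <- flux[incubations$phase == "light"]
  dark <- incubations[incubations$phase == "dark", c("sample_id"), drop = FALSE]
  dark$dark_flux <- flux[incubations$phase == "dark"]
  merged <- merge(light, dark, by = "sample_id")
  n_drop <- (nrow(light) - nrow(merged)) + (nrow(dark) - nrow(merged))
  if (n_drop > 0) {
    warning(sprintf("%d incubation record(s) lacked the paired phase and were dropped", n_drop))
  }
  est <- assemble_pn_r_pg(merged$light_flux, merged$dark_flux)
  out <- cbind(merged[, c("sample_id", "group", "site", "season")], est,
               merged[, c("light_flux", "dark_flux")])
  out[order(out$sample_id), , drop = FALSE]
}
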