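# Upscaling: organism-level fluxes -> seafloor-area contributions
# (c_i = p_i * s_i * b_i * r) and daily ecosystem production under a
# 12 h light / 12 h dark cycle.

#' Seafloor-area contribution of a group's flux
#'
#' Converts a flux per m^2 of 3D specimen surface into a flux per m^2 of
#' planar seafloor:
#' \deqn{c_i = p_i \cdot s_i \cdot b_i \cdot r}
#' where \eqn{s_i} is the group's mean 2D-to-3D surface conversion factor,
#' \eqn{b_i} its planar benthic coverage (0--1) and \eqn{r} the site rugosity
#' factor. Vectorized; \code{b = 0} gives exactly 0.
#'
#' @param p flux in mmol O2 m^-2 (3D specimen area) h^-1 (signed).
#' @param s conversion factor (>= 1).
#' @param b coverage proportion (0--1).
#' @param r rugosity factor (>= 1).
#' @return Contribution in mmol O2 m^-2 (planar seafloor) h^-1.
#' @export
contribution <- function(p, s, b, r) {
  if (any(!is.finite(p))) stop_config("p must be finite")
  if (any(s < 1)) stop_config("s must be >= 1")
  if (any(b < 0 | b > 1)) stop_config("b must be in [0, 1]")
  if (any(r < 1)) stop_config("r must be >= 1")
  p * s * b * r
}

#' Daily ecosystem production from hourly group contributions
#'
#' Sums group contributions and extrapolates to a 12 h light / 12 h dark
#' cycle. Gross production always accumulates over the 12 lit hours:
#' \code{daily_pg = 12 * sum(c_g)} with \code{c_g = c_n + c_resp}. Two
#' conventions for daily net production are provided: \code{"net_24h"}
#' (default) also charges the 12 dark hours with respiration,
#' \code{daily_pn = 12 * sum(c_n) - 12 * sum(c_resp)}; \code{"net_light_only"}
#' counts only the lit hours, \code{daily_pn = 12 * sum(c_n)}.
#'
#' @param c_n hourly net contributions per group (mmol O2 m^-2 seafloor
#'   h^-1).
#' @param c_resp hourly respiration contributions per group (positive
#'   magnitudes, same units).
#' @param convention \code{"net_24h"} or \code{"net_light_only"}.
#' @return list with \code{daily_pn}, \code{daily_pg} (mmol O2 m^-2 seafloor
#'   d^-1) and \code{convention}.
#' @export
daily_totals <- function(c_n, c_resp, convention = c("net_24h", "net_light_only")) {
  convention <- match.arg(convention)
  if (length(c_n) != length(c_resp)) {
    stop_config("c_n and c_resp must align group-wise")
  }
  if (any(!is.finite(c_n)) || any(!is.finite(c_resp))) stop_config("contributions must be finite")
  sum_n <- sum(c_n)
  sum_r <- sum(c_resp)
  daily_pg <- 12 * (sum_n + sum_r)
  daily_pn <- if (convention == "net_24h") 12 * sum_n - 12 * sum_r else 12 * sum_n
  list(daily_pn = daily_pn, daily_pg = daily_pg, convention = convention)
}

# mix-weighted conversion factor per cover category: coral genera are
# averaged with the configured mix ratio; turf and sand carry s = 1.
category_s_factors <- function(conversion_factors, coral_mix) {
  s_col <- if ("s" %in% names(conversion_factors)) "s" else "mean"
  s_map <- stats::setNames(conversion_factors[[s_col]], conversion_factors$group)
  need <- c("coral_montastraea", "coral_diploria", "macroalgae", "turf", "cca", "sand")
  miss <- setdiff(need, names(s_map))
  if (length(miss) > 0) stop_config("missing conversion factor(s): %s", paste(miss, collapse = ", "))
  c(coral = unname(coral_mix["coral_montastraea"] * s_map["coral_montastraea"] +
                     coral_mix["coral_diploria"] * s_map["coral_diploria"]),
    macroalgae = unname(s_map["macroalgae"]),
    turf = unname(s_map["turf"]),
    cca = unname(s_map["cca"]),
    sand = unname(s_map["sand"]))
}

#' Per-specimen seafloor contributions
#'
#' Applies \code{\link{contribution}} to every specimen flux: each specimen's
#' P_n, R and P_g are multiplied by the cover category's conversion factor
#' (coral genera averaged with \code{coral_mix}), the (site, season, category)
#' coverage and the site rugosity factor. Per-specimen rows are retained for
#' downstream inference; the "other" cover category never enters.
#'
#' @param fluxes data.frame from \code{\link{compute_fluxes}}.
#' @param coverage data.frame with columns site, season, category, b_mean
#'   (from \code{\link{coverage_from_transects}}).
#' @param rugosity data.frame with columns site, r.
#' @param conversion_factors data.frame with columns group and s (or mean).
#' @param coral_mix named split of coral cover between the two genera.
#' @return data.frame: sample_id, group, category, site, season, c_n, c_resp,
#'   c_g (mmol O2 m^-2 planar seafloor h^-1).
#' @export
contribution_table <- function(fluxes, coverage, rugosity, conversion_factors,
                               coral_mix = c(coral_montastraea = 0.5,
                                             coral_diploria = 0.5)) {
  s_cat <- category_s_factors(conversion_factors, coral_mix)
  r_map <- stats::setNames(rugosity$r, rugosity$site)
  if (!all(unique(fluxes$site) %in% names(r_map))) {
    stop_config("missing rugosity factor for site(s): %s",
                paste(setdiff(unique(fluxes$site), names(r_map)), collapse = ", "))
  }
  category <- group_to_category(fluxes$group)
  bkey <- paste(coverage$site, coverage$season, coverage$category)
  b_map <- stats::setNames(coverage$b_mean, bkey)
  want <- paste(fluxes$site, fluxes$season, category)
  if (!all(want %in% names(b_map))) {
    stop_config("missing coverage for cell(s): %s",
                paste(unique(setdiff(want, names(b_map))), collapse = "; "))
  }
  s <- unname(s_cat[category])
  b <- unname(b_map[want])
  r <- unname(r_map[fluxes$site])
  out <- data.frame(
    sample_id = fluxes$sample_id, group = fluxes$group, category = category,
    site = fluxes$site, season = fluxes$season,
    c_n = contribution(fluxes$p_n, s, b, r),
    c_resp = contribution(fluxes$resp, s, b, r),
    stringsAsFactors = FALSE
  )
  out$c_g <- out$c_n + out$c_resp
  out
}

#' Daily ecosystem production per site and season
#'
#' Averages per-specimen contributions within each cover category (pooling
#' coral genera), then applies \code{\link{daily_totals}} over categories per
#' (site, season).
#'
#' @param contributions data.frame from \code{\link{contribution_table}}.
#' @param convention passed to \code{\link{daily_totals}}.
#' @return data.frame: site, season, daily_pn, daily_pg, convention.
#' @export
daily_production <- function(contributions, convention = "net_24h") {
  cells <- unique(contributions[, c("site", "season")])
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- contributions[contributions$site == cells$site[i] &
                           contributions$season == cells$season[i], ]
    cn <- tapply(sel$c_n, sel$category, mean)
    cr <- tapply(sel$c_resp, sel$category, mean)
    dt <- daily_totals(as.numeric(cn), as.numeric(cr), convention)
    data.frame(site = cells$site[i], season = cells$season[i],
               daily_pn = dt$daily_pn, daily_pg = dt$daily_pg,
               convention = dt$convention, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
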