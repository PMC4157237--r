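#' Default synthetic scenario for an upwelling-influenced fringing reef
#'
#' Builds the full parameterization of the synthetic-data generator: per-cell
#' flux means and SDs, benthic cover probabilities, 2D-to-3D surface
#' conversion factors, site rugosity, logger (temperature / light) regimes,
#' and replicate counts. Defaults describe two sites (a current/wave-exposed
#' site \code{EXP} and a sheltered site \code{SHE}) across a non-upwelling
#' (\code{NoUp}) and an upwelling (\code{Up}) season.
#'
#' Anchor values: coral net production 16 and gross production 19
#' mmol O2 m^-2 specimen area h^-1 during non-upwelling and net production 12
#' during upwelling; algal turf net production 19 during upwelling (about
#' two-fold its non-upwelling rate); coral cover 41\% / 39\% at the exposed
#' site; sheltered-site macroalgal cover 47\% during upwelling; rugosity
#' factors 1.32 (EXP) and 1.53 (SHE); conversion factors 1.34 (Montastraea),
#' 2.28 (Diploria), 4.29 (macroalgae), 2.10 (CCA); incubation light regimes
#' of 146 and 230 umol photons m^-2 s^-1 PAR. Values the field study does not
#' print (e.g. macroalgal and sediment individual rates, respiration
#' magnitudes, cover of the remaining categories) are fixed at realistic
#' magnitudes consistent with the reported daily ranges; see the methods
#' vignette for the reasoning.
#'
#' @param n_replicates specimens per (group, site, season) cell; each
#'   specimen gets one light and one dark incubation.
#' @param n_blanks seawater-only blank incubations per (site, season, phase).
#' @param o2_start_mg_l common starting O2 concentration (mg L^-1).
#' @param lux_to_par_k lx -> PAR conversion constant used to express logger
#'   light regimes (stored in lx so the generator emits raw logger units).
#' @param rng_seed integer seed recorded in the scenario.
#'
#' @return An object of class \code{reef_scenario}: a list with components
#'   \code{flux_params}, \code{cover_probs}, \code{conversion_factors},
#'   \code{rugosity}, \code{logger}, \code{specimen}, \code{blank_drift},
#'   and scalar settings.
#' @export
#' @examples
#' sc <- default_scenario()
#' print(sc)
default_scenario <- function(n_replicates = 10, n_blanks = 3,
                             o2_start_mg_l = 6.5, lux_to_par_k = 0.0185,
                             rng_seed = 1L) {
  # per-group flux distributions (mmol O2 m^-2 3D specimen area h^-1);
  # dark-phase means are negative (O2 consumption)
  base <- rbind(
    data.frame(group = "coral_montastraea", season = "NoUp", light_mean = 16,  light_sd = 4,   dark_mean = -3,   dark_sd = 1),
    data.frame(group = "coral_montastraea", season = "Up",   light_mean = 12,  light_sd = 3,   dark_mean = -5.4, dark_sd = 1.5),
    data.frame(group = "coral_diploria",    season = "NoUp", light_mean = 16,  light_sd = 4,   dark_mean = -3,   dark_sd = 1),
    data.frame(group = "coral_diploria",    season = "Up",   light_mean = 12,  light_sd = 3,   dark_mean = -5.4, dark_sd = 1.5),
    data.frame(group = "turf",              season = "NoUp", light_mean = 9.5, light_sd = 2.5, dark_mean = -3.5, dark_sd = 1),
    data.frame(group = "turf",              season = "Up",   light_mean = 19,  light_sd = 5,   dark_mean = -3.5, dark_sd = 1),
    data.frame(group = "macroalgae",        season = "NoUp", light_mean = 5,   light_sd = 1.5, dark_mean = -1.5, dark_sd = 0.5),
    data.frame(group = "macroalgae",        season = "Up",   light_mean = 7,   light_sd = 2,   dark_mean = -1.5, dark_sd = 0.5),
    data.frame(group = "cca",               season = "NoUp", light_mean = 3,   light_sd = 1,   dark_mean = -1,   dark_sd = 0.4),
    data.frame(group = "cca",               season = "Up",   light_mean = 2.5, light_sd = 0.8, dark_mean = -1,   dark_sd = 0.4),
    data.frame(group = "sand",              season = "NoUp", light_mean = 0.8, light_sd = 0.5, dark_mean = -0.5, dark_sd = 0.3),
    data.frame(group = "sand",              season = "Up",   light_mean = 0.8, light_sd = 0.5, dark_mean = -0.5, dark_sd = 0.3)
  )
  # same organism-level regime at both sites; site differences enter through
  # coverage and rugosity
  flux_params <- do.call(rbind, lapply(c("EXP", "SHE"), function(site) {
    long <- rbind(
      data.frame(group = base$group, site = site, season = base$season,
                 phase = "light", mean = base$light_mean, sd = base$light_sd),
      data.frame(group = base$group, site = site, season = base$season,
                 phase = "dark", mean = base$dark_mean, sd = base$dark_sd)
    )
    long
  }))
  rownames(flux_params) <- NULL

  cover_probs <- rbind(
    data.frame(site = "EXP", season = "NoUp",
               category = c("coral", "macroalgae", "turf", "cca", "sand", "other"),
               prob = c(0.41, 0.00, 0.20, 0.15, 0.15, 0.09)),
    data.frame(site = "EXP", season = "Up",
               category = c("coral", "macroalgae", "turf", "cca", "sand", "other"),
               prob = c(0.39, 0.05, 0.22, 0.10, 0.15, 0.09)),
    data.frame(site = "SHE", season = "NoUp",
               category = c("coral", "macroalgae", "turf", "cca", "sand", "other"),
               prob = c(0.24, 0.10, 0.26, 0.12, 0.25, 0.03)),
    data.frame(site = "SHE", season = "Up",
               category = c("coral", "macroalgae", "turf", "cca", "sand", "other"),
               prob = c(0.20, 0.47, 0.12, 0.05, 0.13, 0.03))
  )

  conversion_factors <- data.frame(
    group = c("coral_montastraea", "coral_diploria", "macroalgae", "turf", "cca", "sand"),
    mean = c(1.34, 2.28, 4.29, 1.00, 2.10, 1.00),
    sd = c(0.56, 0.16, 0.82, 0.00, 0.89, 0.00)
  )

  rugosity <- data.frame(site = c("EXP", "SHE"), mean = c(1.32, 1.53), sd = c(0.13, 0.12))

  logger <- data.frame(
    season = c("NoUp", "Up"),
    temp_mean = c(29.1, 25.3), temp_sd = c(0.2, 0.3),
    light_lx_mean = c(146, 230) / lux_to_par_k,
    light_lx_sd = c(47, 58) / lux_to_par_k
  )

  # incubation geometry: planar specimen areas (cm^2) and container volumes (L)
  specimen <- data.frame(
    group = c("coral_montastraea", "coral_diploria", "macroalgae", "turf", "cca", "sand"),
    area2d_mean = c(13.16, 13.16, 1.86, 15.63, 7.48, 1.20),
    area2d_sd = c(7.96, 7.96, 0.88, 10.80, 3.60, 0.00),
    area2d_min = c(1.0, 1.0, 0.2, 1.0, 0.5, 1.20),
    volume_l = c(0.6, 0.6, 0.06, 0.6, 0.06, 0.06)
  )

  scenario <- structure(list(
    flux_params = flux_params,
    cover_probs = cover_probs,
    conversion_factors = conversion_factors,
    rugosity = rugosity,
    logger = logger,
    specimen = specimen,
    blank_drift = data.frame(phase = c("light", "dark"),
                             mean = c(0.01, -0.01), sd = c(0.005, 0.005)),
    n_replicates = as.integer(n_replicates),
    n_blanks = as.integer(n_blanks),
    o2_start_mg_l = o2_start_mg_l,
    light_duration_h = c(0.5, 1.0),
    dark_duration_h = 2.0,
    lux_to_par_k = lux_to_par_k,
    coral_mix = c(coral_montastraea = 0.5, coral_diploria = 0.5),
    rng_seed = as.integer(rng_seed)
  ), class = "reef_scenario")
  validate_scenario(scenario)
  scenario
}

#' Validate a synthetic scenario
#'
#' Checks the structural invariants of a \code{reef_scenario}: cover
#' probabilities per (site, season) sum to 1 (an "other" category absorbs the
#' remainder), all SDs are non-negative, conversion-factor and rugosity means
#' are at least 1, replicate counts are at least 1, and flux cells reference
#' known groups/sites/seasons.
#'
#' @param scenario a \code{reef_scenario}.
#' @return The scenario, invisibly; signals an error on violation.
#' @export
validate_scenario <- function(scenario) {
  if (!inherits(scenario, "reef_scenario")) {
    stop_config("not a reef_scenario object")
  }
  cp <- scenario$cover_probs
  sums <- tapply(cp$prob, interaction(cp$site, cp$season, drop = TRUE), sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop_config("cover probabilities must sum to 1 per (site, season); got %s",
                paste(format(sums), collapse = ", "))
  }
  if (any(cp$prob < 0)) stop_config("cover probabilities must be >= 0")
  fp <- scenario$flux_params
  assert_nonneg(fp$sd, "flux_params$sd")
  if (!all(fp$group %in% flux_groups())) {
    stop_config("unknown flux group(s): %s",
                paste(setdiff(fp$group, flux_groups()), collapse = ", "))
  }
  if (!all(fp$phase %in% c("light", "dark"))) stop_config("phase must be light or dark")
  cf <- scenario$conversion_factors
  assert_nonneg(cf$sd, "conversion_factors$sd")
  if (any(cf$mean < 1)) stop_config("conversion factor means must be >= 1")
  rg <- scenario$rugosity
  assert_nonneg(rg$sd, "rugosity$sd")
  if (any(rg$mean < 1)) stop_config("rugosity means must be >= 1")
  assert_nonneg(scenario$logger$temp_sd, "logger$temp_sd")
  assert_nonneg(scenario$logger$light_lx_sd, "logger$light_lx_sd")
  if (scenario$n_replicates < 1L) stop_config("n_replicates must be >= 1")
  if (scenario$n_blanks < 1L) stop_config("n_blanks must be >= 1")
  assert_positive(scenario$o2_start_mg_l, "o2_start_mg_l")
  if (abs(sum(scenario$coral_mix) - 1) > 1e-9 || any(scenario$coral_mix < 0)) {
    stop_config("coral_mix must be a nonnegative split summing to 1")
  }
  invisible(scenario)
}

#' @export
print.reef_scenario <- function(x, ...) {
  cells <- unique(x$flux_params[, c("group", "site", "season")])
  cat("reef_scenario:",
      nrow(cells), "flux cells |",
      x$n_replicates, "replicates/cell |",
      "seed", x$rng_seed, "\n")
  cat("  sites:", paste(unique(x$rugosity$site), collapse = ", "),
      "| seasons:", paste(unique(x$logger$season), collapse = ", "), "\n")
  cat("  groups:", paste(unique(x$flux_params$group), collapse = ", "), "\n")
  invisible(x)
}

#' Read a scenario from a YAML file
#'
#' The YAML file may override any scalar setting of the default scenario
#' (e.g. \code{n_replicates}, \code{o2_start_mg_l}, \code{rng_seed}) and any
#' of the parameter tables. Tables are given as lists of records with the
#' same column names as the corresponding \code{default_scenario()}
#' components (\code{flux_params}, \code{cover_probs},
#' \code{conversion_factors}, \code{rugosity}, \code{logger},
#' \code{specimen}, \code{blank_drift}).
#'
#' @param path path to a YAML scenario file.
#' @return A validated \code{reef_scenario}.
#' @export
read_scenario <- function(path) {
  raw <- yaml::read_yaml(path)
  sc <- default_scenario()
  table_fields <- c("flux_params", "cover_probs", "conversion_factors",
                    "rugosity", "logger", "specimen", "blank_drift")
  for (f in names(raw)) {
    if (f %in% table_fields) {
      recs <- raw[[f]]
      df <- do.call(rbind, lapply(recs, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
      sc[[f]] <- df
    } else if (f %in% names(sc)) {
      val <- raw[[f]]
      if (f %in% c("n_replicates", "n_blanks", "rng_seed")) val <- as.integer(val)
      if (f %in% c("light_duration_h", "coral_mix")) val <- unlist(val)
      if (f == "coral_mix") names(val) <- c("coral_montastraea", "coral_diploria")
      sc[[f]] <- val
    } else {
      stop_config("unknown scenario field in YAML: '%s'", f)
    }
  }
  validate_scenario(sc)
  sc
}
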