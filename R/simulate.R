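# Synthetic input generator: emulates every table the pipeline consumes.

# mean of a Normal(mean, sd) truncated below at `lower`
trunc_norm_mean <- function(mean, sd, lower = 1) {
  ifelse(sd == 0, pmax(mean, lower), {
    a <- (lower - mean) / sd
    mean + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  })
}

#' Effective 2D-to-3D conversion factors of a scenario
#'
#' The generator draws surface-pair ratios from Normal(mean, sd) truncated at
#' 1, so the population mean ratio -- what the survey stage estimates and the
#' incubation generator uses to back-compute concentrations -- is the
#' truncated-normal mean, which exceeds the location parameter when the
#' truncation bites (e.g. Montastraea-type corals with their wide ratio
#' spread). With sd = 0 the two coincide.
#'
#' @param scenario a \code{reef_scenario}.
#' @return data.frame with columns group and s.
#' @export
scenario_s_factors <- function(scenario) {
  cf <- scenario$conversion_factors
  data.frame(group = cf$group, s = trunc_norm_mean(cf$mean, cf$sd, 1),
             stringsAsFactors = FALSE)
}

# normal draws truncated below at `lower` (rejection sampling; sd = 0
# degenerates to the clamped mean)
rtnorm_min <- function(n, mean, sd, lower) {
  if (sd == 0) return(rep(max(mean, lower), n))
  out <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- stats::rnorm(length(todo), mean, sd)
    ok <- draw >= lower
    out[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  out
}

#' Generate blank (seawater-only) incubation records
#'
#' Blanks quantify planktonic/microbial activity in the incubation water.
#' Drift rates are drawn per phase from the scenario's \code{blank_drift}
#' distribution (mg O2 L^-1 h^-1), small relative to specimen signal.
#'
#' @param scenario a \code{reef_scenario}.
#' @param seed optional integer; if given, \code{set.seed} is called first.
#' @return data.frame with columns sample_id, site, season, phase,
#'   o2_start_mg_l, o2_end_mg_l, duration_h, volume_l.
#' @export
gen_blanks <- function(scenario, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  grid <- expand.grid(site = unique(scenario$rugosity$site),
                      season = scenario$logger$season,
                      phase = c("light", "dark"),
                      rep = seq_len(scenario$n_blanks),
                      stringsAsFactors = FALSE)
  dr <- scenario$blank_drift
  out <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    d <- dr[dr$phase == g$phase, ]
    duration <- if (g$phase == "light") {
      stats::runif(1, scenario$light_duration_h[1], scenario$light_duration_h[2])
    } else scenario$dark_duration_h
    drift <- stats::rnorm(1, d$mean, d$sd)
    data.frame(
      sample_id = sprintf("BL_%s_%s_%s_%02d", g$site, g$season, g$phase, g$rep),
      site = g$site, season = g$season, phase = g$phase,
      o2_start_mg_l = scenario$o2_start_mg_l,
      o2_end_mg_l = scenario$o2_start_mg_l + drift * duration,
      duration_h = duration, volume_l = 0.6,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Generate specimen incubation records (with matching blanks)
#'
#' For each (group, site, season) cell, draws a target net flux per specimen
#' and phase from the scenario's Normal(mean, sd) and back-computes the end
#' O2 concentration from start concentration, container volume, duration,
#' planar area and the group's effective 2D-to-3D conversion factor (see
#' \code{\link{scenario_s_factors}}), so that the
#' flux pipeline (blank subtraction included) recovers the drawn flux
#' exactly. The realized mean blank rate per (site, season, phase) is used in
#' the inversion, making the round trip exact even though blanks are noisy.
#' Each specimen receives one light and one dark incubation sharing the same
#' planar area, mirroring paired field incubations.
#'
#' @param scenario a \code{reef_scenario}.
#' @param cells optional data.frame with columns group, site, season
#'   selecting which cells to generate (default: all cells present in the
#'   scenario's \code{flux_params}). Unknown keys are an error.
#' @param seed optional integer seed.
#' @return list with elements \code{incubations} and \code{blanks} (see
#'   \code{\link{gen_blanks}}); incubations have columns sample_id, group,
#'   site, season, phase, o2_start_mg_l, o2_end_mg_l, duration_h, volume_l,
#'   area2d_cm2, plus the drawn target flux in \code{true_flux} (kept for
#'   validation; dropped on CSV write).
#' @export
gen_incubations <- function(scenario, cells = NULL, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  fp <- scenario$flux_params
  all_cells <- unique(fp[, c("group", "site", "season")])
  if (is.null(cells)) {
    cells <- all_cells
  } else {
    key <- paste(cells$group, cells$site, cells$season)
    known <- paste(all_cells$group, all_cells$site, all_cells$season)
    if (!all(key %in% known)) {
      stop_config("unknown (group, site, season) cell(s): %s",
                  paste(setdiff(key, known), collapse = "; "))
    }
  }

  blanks <- gen_blanks(scenario)
  # realized mean blank rate (mg L^-1 h^-1) per site/season/phase
  brate <- (blanks$o2_end_mg_l - blanks$o2_start_mg_l) / blanks$duration_h
  bkey <- paste(blanks$site, blanks$season, blanks$phase)
  blank_mean <- tapply(brate, bkey, mean)

  spec_tab <- scenario$specimen
  cf <- scenario_s_factors(scenario)
  n_rep <- scenario$n_replicates
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- cells[i, ]
    sp <- spec_tab[spec_tab$group == cell$group, ]
    s_mean <- cf$s[cf$group == cell$group]
    area2d <- rtnorm_min(n_rep, sp$area2d_mean, sp$area2d_sd, sp$area2d_min)
    ids <- sprintf("%s_%s_%s_%02d", cell$site, cell$season, cell$group, seq_len(n_rep))
    phase_rows <- lapply(c("light", "dark"), function(phase) {
      par_row <- fp[fp$group == cell$group & fp$site == cell$site &
                      fp$season == cell$season & fp$phase == phase, ]
      if (nrow(par_row) != 1) {
        stop_config("scenario has %d flux parameter rows for (%s, %s, %s, %s)",
                    nrow(par_row), cell$group, cell$site, cell$season, phase)
      }
      target <- stats::rnorm(n_rep, par_row$mean, par_row$sd)
      duration <- if (phase == "light") {
        stats::runif(n_rep, scenario$light_duration_h[1], scenario$light_duration_h[2])
      } else rep(scenario$dark_duration_h, n_rep)
      b <- blank_mean[[paste(cell$site, cell$season, phase)]]
      # invert the flux equation: flux [mmol m^-2(3D) h^-1] -> delta mg L^-1
      area3d_m2 <- area2d * 1e-4 * s_mean
      rate_mg <- target * area3d_m2 / sp$volume_l * O2_MOLAR_MASS + b
      data.frame(
        sample_id = ids, group = cell$group, site = cell$site,
        season = cell$season, phase = phase,
        o2_start_mg_l = scenario$o2_start_mg_l,
        o2_end_mg_l = scenario$o2_start_mg_l + rate_mg * duration,
        duration_h = duration, volume_l = sp$volume_l, area2d_cm2 = area2d,
        true_flux = target, stringsAsFactors = FALSE
      )
    })
    rows[[i]] <- do.call(rbind, phase_rows)
  }
  inc <- do.call(rbind, rows)
  rownames(inc) <- NULL
  if (any(inc$o2_end_mg_l < 0)) {
    warning("some generated end concentrations fell below 0 mg L^-1; ",
            "scenario fluxes may be unrealistically strong for the container volume")
  }
  list(incubations = inc, blanks = blanks)
}

#' Generate line-point-intercept transect label sequences
#'
#' Each transect is 101 independent categorical draws (a 50 m tape read every
#' 0.5 m) from the (site, season) cover probabilities.
#'
#' @param scenario a \code{reef_scenario}.
#' @param site,season cell selectors.
#' @param n_transects number of transects.
#' @param seed optional integer seed.
#' @return data.frame with columns site, season, transect_id,
#'   point_index (0--100), label.
#' @export
gen_transects <- function(scenario, site, season, n_transects, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  cp <- scenario$cover_probs
  sel <- cp[cp$site == site & cp$season == season, ]
  if (nrow(sel) == 0) stop_config("no cover probabilities for (%s, %s)", site, season)
  if (abs(sum(sel$prob) - 1) > 1e-9) {
    stop_config("cover probabilities for (%s, %s) sum to %.12f, not 1", site, season, sum(sel$prob))
  }
  n_pts <- 101L
  out <- lapply(seq_len(n_transects), function(t) {
    data.frame(site = site, season = season, transect_id = t,
               point_index = 0:(n_pts - 1L),
               label = sample(sel$category, n_pts, replace = TRUE, prob = sel$prob),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Generate chain-method rugosity measurements
#'
#' Draws chain/linear ratios from the site's Normal(mean, sd) truncated at 1
#' (a chain laid over relief can never be shorter than the tape) and reports
#' chain lengths over a 10 m linear sub-transect.
#'
#' @param scenario a \code{reef_scenario}.
#' @param site site code.
#' @param n number of sub-transects.
#' @param seed optional integer seed.
#' @return data.frame with columns site, chain_m, linear_m.
#' @export
gen_rugosity <- function(scenario, site, n, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  rg <- scenario$rugosity[scenario$rugosity$site == site, ]
  if (nrow(rg) == 0) stop_config("no rugosity parameters for site '%s'", site)
  ratio <- rtnorm_min(n, rg$mean, rg$sd, 1)
  linear <- 10
  data.frame(site = site, chain_m = ratio * linear, linear_m = linear,
             stringsAsFactors = FALSE)
}

#' Generate a temperature/light logger series
#'
#' I.i.d. normal draws per season at 2-minute spacing, in raw logger units
#' (degrees C and lx); light readings are floored at 0 lx.
#'
#' @param scenario a \code{reef_scenario}.
#' @param season season code.
#' @param n_samples number of readings.
#' @param seed optional integer seed.
#' @return data.frame with columns season, t_min, temp_c, light_lx.
#' @export
gen_logger <- function(scenario, season, n_samples, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  if (n_samples < 1) stop_config("n_samples must be >= 1")
  lg <- scenario$logger[scenario$logger$season == season, ]
  if (nrow(lg) == 0) stop_config("no logger parameters for season '%s'", season)
  data.frame(
    season = season,
    t_min = 2 * (seq_len(n_samples) - 1),
    temp_c = stats::rnorm(n_samples, lg$temp_mean, lg$temp_sd),
    light_lx = pmax(0, stats::rnorm(n_samples, lg$light_lx_mean, lg$light_lx_sd)),
    stringsAsFactors = FALSE
  )
}

#' Generate paired 2D/3D specimen surface areas
#'
#' Planar areas follow the group's specimen-size distribution; the 3D area is
#' the planar area times a conversion-factor draw (Normal truncated at 1).
#'
#' @param scenario a \code{reef_scenario}.
#' @param group a flux group (see \code{\link{flux_groups}}).
#' @param n number of specimen pairs.
#' @param seed optional integer seed.
#' @return data.frame with columns group, area2d_cm2, area3d_cm2.
#' @export
gen_surface_pairs <- function(scenario, group, n, seed = NULL) {
  validate_scenario(scenario)
  if (!is.null(seed)) set.seed(seed)
  if (n < 1) stop_config("n must be >= 1")
  cf <- scenario$conversion_factors[scenario$conversion_factors$group == group, ]
  sp <- scenario$specimen[scenario$specimen$group == group, ]
  if (nrow(cf) == 0 || nrow(sp) == 0) stop_config("unknown group '%s'", group)
  area2d <- rtnorm_min(n, sp$area2d_mean, sp$area2d_sd, sp$area2d_min)
  ratio <- rtnorm_min(n, cf$mean, cf$sd, 1)
  data.frame(group = group, area2d_cm2 = area2d, area3d_cm2 = area2d * ratio,
             stringsAsFactors = FALSE)
}

#' Generate the full set of pipeline input tables
#'
#' Runs every generator under a single seed: paired incubations and blanks
#' for all scenario cells, transects, rugosity sub-transects, logger series
#' for both seasons and surface-area pairs for all groups. Identical
#' scenario + seed gives byte-identical tables on CSV serialization.
#'
#' @param scenario a \code{reef_scenario}.
#' @param seed integer seed (default: the scenario's \code{rng_seed}).
#' @param n_transects transects per (site, season).
#' @param n_rugosity chain sub-transects per site.
#' @param n_logger logger readings per season.
#' @param n_pairs surface-area pairs per group.
#' @return named list of data.frames: incubations, blanks, transects,
#'   rugosity, logger, surface_pairs.
#' @export
simulate_inputs <- function(scenario, seed = scenario$rng_seed,
                            n_transects = 3, n_rugosity = 9,
                            n_logger = 500, n_pairs = 10) {
  validate_scenario(scenario)
  set.seed(seed)
  inc <- gen_incubations(scenario)
  sites <- unique(scenario$rugosity$site)
  seasons <- scenario$logger$season
  transects <- do.call(rbind, lapply(sites, function(si) {
    do.call(rbind, lapply(seasons, function(se) {
      gen_transects(scenario, si, se, n_transects)
    }))
  }))
  rugosity <- do.call(rbind, lapply(sites, function(si) gen_rugosity(scenario, si, n_rugosity)))
  logger <- do.call(rbind, lapply(seasons, function(se) gen_logger(scenario, se, n_logger)))
  pairs <- do.call(rbind, lapply(unique(scenario$conversion_factors$group),
                                 function(g) gen_surface_pairs(scenario, g, n_pairs)))
  rownames(transects) <- rownames(rugosity) <- rownames(logger) <- rownames(pairs) <- NULL
  list(incubations = inc$incubations, blanks = inc$blanks, transects = transects,
       rugosity = rugosity, logger = logger, surface_pairs = pairs)
}

#' Write simulated input tables to CSV
#'
#' Writes incubations.csv, blanks.csv, transects.csv, rugosity.csv,
#' logger.csv and surface_pairs.csv into \code{out_dir} with canonical column
#' sets (the generator-internal \code{true_flux} column is dropped).
#'
#' @param tables list as returned by \code{\link{simulate_inputs}}.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, the vector of file paths written.
#' @export
write_simulation <- function(tables, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  inc <- tables$incubations
  inc <- inc[, c("sample_id", "group", "site", "season", "phase",
                 "o2_start_mg_l", "o2_end_mg_l", "duration_h", "volume_l", "area2d_cm2")]
  files <- c(
    incubations = file.path(out_dir, "incubations.csv"),
    blanks = file.path(out_dir, "blanks.csv"),
    transects = file.path(out_dir, "transects.csv"),
    rugosity = file.path(out_dir, "rugosity.csv"),
    logger = file.path(out_dir, "logger.csv"),
    surface_pairs = file.path(out_dir, "surface_pairs.csv")
  )
  utils::write.csv(inc, files[["incubations"]], row.names = FALSE)
  utils::write.csv(tables$blanks, files[["blanks"]], row.names = FALSE)
  utils::write.csv(tables$transects, files[["transects"]], row.names = FALSE)
  utils::write.csv(tables$rugosity, files[["rugosity"]], row.names = FALSE)
  utils::write.csv(tables$logger, files[["logger"]], row.names = FALSE)
  utils::write.csv(tables$surface_pairs, files[["surface_pairs"]], row.names = FALSE)
  invisible(files)
}
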