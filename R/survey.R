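# Benthic survey geometry: cover from line-point-intercept transects,
# rugosity from chain measurements, 2D->3D conversion factors from paired
# areas, and the classical cover statistics.

#' Measurement positions along a line-point-intercept transect
#'
#' @param length_m tape length in metres.
#' @param spacing_m interval between points; must divide the length.
#' @return Numeric vector of positions 0, spacing, ..., length (inclusive),
#'   i.e. length/spacing + 1 points: a 50 m tape at 0.5 m yields 101 points.
#' @export
transect_positions <- function(length_m, spacing_m) {
  assert_positive(length_m, "length_m")
  assert_positive(spacing_m, "spacing_m")
  k <- length_m / spacing_m
  if (abs(k - round(k)) > 1e-9) {
    stop_config("spacing %.6g does not divide transect length %.6g", spacing_m, length_m)
  }
  seq(0, length_m, by = spacing_m)
}

#' Benthic coverage from transect label sequences
#'
#' Per-transect category proportions (count / points-per-transect) and their
#' mean and SD over transects per (site, season). All transects must have the
#' same number of points and only labels from the closed vocabulary.
#'
#' @param transects data.frame with columns site, season, transect_id, label
#'   (one row per point).
#' @param categories closed label vocabulary (default
#'   \code{\link{cover_categories}}).
#' @param n_points required points per transect (default 101).
#' @return list with \code{per_transect} (site, season, transect_id,
#'   category, prop) and \code{coverage} (site, season, category, b_mean,
#'   b_sd, n_transects). Within each transect the proportions over all
#'   categories sum to 1 exactly.
#' @export
coverage_from_transects <- function(transects, categories = cover_categories(),
                                    n_points = 101L) {
  unknown <- setdiff(unique(transects$label), categories)
  if (length(unknown) > 0) {
    stop_config("unknown transect label(s): %s", paste(unknown, collapse = ", "))
  }
  key <- paste(transects$site, transects$season, transects$transect_id, sep = "\r")
  counts <- table(key, factor(transects$label, levels = categories))
  lens <- rowSums(counts)
  if (any(lens != n_points)) {
    stop_config("every transect must have exactly %d points; found lengths %s",
                n_points, paste(unique(lens), collapse = ", "))
  }
  idx <- unique(transects[, c("site", "season", "transect_id")])
  idx <- idx[match(rownames(counts), paste(idx$site, idx$season, idx$transect_id, sep = "\r")), ]
  n_t <- nrow(idx)
  per <- data.frame(
    site = rep(idx$site, times = length(categories)),
    season = rep(idx$season, times = length(categories)),
    transect_id = rep(idx$transect_id, times = length(categories)),
    category = rep(categories, each = n_t),
    prop = as.vector(counts[, categories]) / n_points,
    stringsAsFactors = FALSE
  )
  per <- per[order(per$site, per$season, per$transect_id, match(per$category, categories)), ]
  rownames(per) <- NULL
  agg_mean <- stats::aggregate(prop ~ site + season + category, data = per, FUN = mean)
  agg_sd <- stats::aggregate(prop ~ site + season + category, data = per,
                             FUN = stats::sd)
  agg_n <- stats::aggregate(prop ~ site + season + category, data = per, FUN = length)
  cov <- agg_mean
  names(cov)[names(cov) == "prop"] <- "b_mean"
  cov$b_sd <- agg_sd$prop
  cov$n_transects <- agg_n$prop
  list(per_transect = per, coverage = cov)
}

#' Rugosity factor from chain measurements
#'
#' The chain method drapes a fine chain over the substrate along a linear
#' sub-transect; the ratio chain length / linear length (>= 1) measures
#' substrate relief. Ratios below 1 are physically impossible and treated as
#' measurement error: clamped to 1 with a warning.
#'
#' @param chain_m,linear_m paired lengths in metres (vectorized).
#' @param site site code attached to the result.
#' @return list with \code{site}, \code{r} (mean ratio), \code{sd},
#'   \code{ratios} (per-sub-transect values after clamping), \code{n}.
#' @export
rugosity_factor <- function(chain_m, linear_m, site) {
  assert_positive(chain_m, "chain_m")
  assert_positive(linear_m, "linear_m")
  ratios <- chain_m / linear_m
  if (any(ratios < 1)) {
    warning(sprintf("%d chain ratio(s) < 1 clamped to 1 (chain shorter than tape)",
                    sum(ratios < 1)))
    ratios[ratios < 1] <- 1
  }
  list(site = site, r = mean(ratios), sd = stats::sd(ratios), ratios = ratios,
       n = length(ratios))
}

#' 2D-to-3D surface conversion factor from paired areas
#'
#' @param area2d_cm2,area3d_cm2 paired planar and 3D surface areas
#'   (vectorized, > 0).
#' @param group group label attached to the result.
#' @return list with \code{group}, \code{s} (mean per-specimen 3D/2D ratio),
#'   \code{sd}, \code{n}.
#' @export
conversion_factor_estimate <- function(area2d_cm2, area3d_cm2, group) {
  assert_positive(area2d_cm2, "area2d_cm2")
  assert_positive(area3d_cm2, "area3d_cm2")
  ratios <- area3d_cm2 / area2d_cm2
  list(group = group, s = mean(ratios), sd = stats::sd(ratios), n = length(ratios))
}

#' Classical two-way cover statistics
#'
#' For one category's per-transect proportions: Kolmogorov-Smirnov normality
#' check of residuals against the fitted normal, Brown-Forsythe/Levene
#' homogeneity check (ANOVA on absolute deviations from cell medians),
#' two-way ANOVA (type-II sums of squares) with factors site and season, and
#' -- when the interaction is significant at \code{alpha} -- all pairwise
#' cell comparisons with Bonferroni-multiplied p-values (capped at 1).
#'
#' @param per_transect data.frame with columns site, season, prop (one row
#'   per transect).
#' @param alpha significance level gating the post hoc comparisons.
#' @return list with \code{anova} (data.frame: term, F, p), \code{ks}
#'   (statistic, p), \code{levene} (F, p), and \code{pairwise} (NULL unless
#'   the interaction is significant: data.frame pair, diff, p_raw, p_adj).
#' @export
classic_cover_tests <- function(per_transect, alpha = 0.05) {
  d <- data.frame(site = factor(per_transect$site),
                  season = factor(per_transect$season),
                  prop = per_transect$prop)
  cell <- interaction(d$site, d$season, drop = TRUE)
  if (any(table(cell) < 2)) {
    stop_config("each site x season cell needs >= 2 transects")
  }
  fit <- stats::lm(prop ~ site * season, data = d)
  a2 <- car::Anova(fit, type = 2)
  terms <- rownames(a2)
  keep <- terms != "Residuals"
  anova_tab <- data.frame(term = terms[keep], F = a2[keep, "F value"],
                          p = a2[keep, "Pr(>F)"])
  res <- stats::residuals(fit)
  ks <- suppressWarnings(stats::ks.test(res, "pnorm", mean = mean(res),
                                        sd = stats::sd(res)))
  lev <- car::leveneTest(prop ~ site * season, data = d, center = stats::median)
  pairwise <- NULL
  p_int <- anova_tab$p[anova_tab$term == "site:season"]
  if (length(p_int) == 1 && !is.na(p_int) && p_int < alpha) {
    cells <- levels(cell)
    combs <- utils::combn(cells, 2)
    n_comp <- ncol(combs)
    pairwise <- do.call(rbind, lapply(seq_len(n_comp), function(j) {
      g1 <- d$prop[cell == combs[1, j]]
      g2 <- d$prop[cell == combs[2, j]]
      tt <- stats::t.test(g1, g2, var.equal = TRUE)
      data.frame(pair = paste(combs[1, j], "vs", combs[2, j]),
                 diff = mean(g1) - mean(g2),
                 p_raw = tt$p.value,
                 p_adj = min(1, tt$p.value * n_comp),
                 stringsAsFactors = FALSE)
    }))
  }
  list(anova = anova_tab,
       ks = list(statistic = unname(ks$statistic), p = ks$p.value),
       levene = list(F = lev[1, "F value"], p = lev[1, "Pr(>F)"]),
       pairwise = pairwise)
}
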