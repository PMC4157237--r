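# Survey geometry: transect positions, coverage, rugosity, conversion
# factors and the classical cover statistics

mk_transect <- function(labels, site = "EXP", season = "NoUp", id = 1) {
  data.frame(site = site, season = season, transect_id = id,
             point_index = seq_along(labels) - 1, label = labels,
             stringsAsFactors = FALSE)
}

test_that("transect positions are inclusive endpoints at fixed spacing", {
  expect_length(transect_positions(50, 0.5), 101)
  expect_length(transect_positions(10, 0.5), 21)
  expect_equal(transect_positions(7, 7), c(0, 7))
  expect_error(transect_positions(50, 0.7), "does not divide")
})

test_that("coverage is the per-transect count ratio, averaged over transects", {
  labs <- c(rep("coral", 40), rep("other", 61))
  cov <- coverage_from_transects(mk_transect(labs))
  per <- cov$per_transect
  expect_equal(per$prop[per$category == "coral"], 40 / 101)
  # proportions over all categories sum to 1 exactly per transect
  expect_equal(sum(per$prop), 1)

  all_sand <- coverage_from_transects(mk_transect(rep("sand", 101)))
  expect_equal(all_sand$coverage$b_mean[all_sand$coverage$category == "sand"], 1)

  # three transects with coral proportions 0.2, 0.3, 0.4 -> b = 0.3
  tr <- rbind(
    mk_transect(c(rep("coral", 20), rep("other", 81)), id = 1),
    mk_transect(c(rep("coral", 30), rep("other", 71)), id = 2),
    mk_transect(c(rep("coral", 40), rep("other", 61)), id = 3)
  )
  # use a 101-point vocabulary-consistent set with exact proportions:
  # 20/101 etc. are not 0.2; construct directly on a 10-point transect
  tr10 <- rbind(
    mk_transect(c(rep("coral", 2), rep("other", 8)), id = 1),
    mk_transect(c(rep("coral", 3), rep("other", 7)), id = 2),
    mk_transect(c(rep("coral", 4), rep("other", 6)), id = 3)
  )
  cov10 <- coverage_from_transects(tr10, n_points = 10L)
  b <- cov10$coverage
  expect_equal(b$b_mean[b$category == "coral"], 0.3)

  expect_error(coverage_from_transects(mk_transect(rep("kelp", 101))), "kelp")
  expect_error(coverage_from_transects(mk_transect(rep("coral", 90))), "101")
})

test_that("coverage estimator is unbiased under multinomial sampling", {
  sc <- default_scenario()
  sc$cover_probs <- data.frame(site = "EXP", season = "NoUp",
                               category = c("coral", "other"),
                               prob = c(0.3, 0.7))
  tr <- gen_transects(sc, "EXP", "NoUp", 2000, seed = 31)
  cov <- coverage_from_transects(tr)
  b <- cov$coverage$b_mean[cov$coverage$category == "coral"]
  se <- sqrt(0.3 * 0.7 / (2000 * 101))
  expect_lt(abs(b - 0.3), 3 * se)
})

test_that("rugosity factors are chain/linear ratios clamped at 1", {
  rf <- rugosity_factor(13.2, 10, "EXP")
  expect_equal(rf$r, 1.32)
  expect_equal(rugosity_factor(10, 10, "EXP")$r, 1)
  expect_equal(rugosity_factor(c(15.0, 15.3, 15.6), 10, "SHE")$r, 1.53)
  expect_warning(rf2 <- rugosity_factor(c(9.8, 12), 10, "EXP"), "clamped")
  expect_equal(rf2$ratios, c(1, 1.2))
  expect_error(rugosity_factor(-1, 10, "EXP"), "chain_m")
})

test_that("conversion factors are mean 3D/2D ratios", {
  expect_equal(conversion_factor_estimate(10, 22.8, "coral_diploria")$s, 2.28)
  expect_equal(conversion_factor_estimate(5, 21.45, "macroalgae")$s, 4.29)
  expect_equal(conversion_factor_estimate(c(4, 9), c(4, 9), "turf")$s, 1)
  expect_error(conversion_factor_estimate(0, 5, "cca"), "area2d")
})

test_that("two-way cover ANOVA matches the closed-form balanced oracle", {
  # balanced 2x2, n = 3 per cell, fixed values
  d <- expand.grid(site = c("EXP", "SHE"), season = c("NoUp", "Up"),
                   rep = 1:3, KEEP.OUT.ATTRS = FALSE)
  set.seed(17)
  d$prop <- round(runif(nrow(d), 0.1, 0.6), 3)
  res <- classic_cover_tests(d)

  # independent closed-form two-way ANOVA sums of squares
  y <- d$prop
  ybar <- mean(y)
  a_means <- tapply(y, d$site, mean)
  b_means <- tapply(y, d$season, mean)
  cell_means <- tapply(y, interaction(d$site, d$season), mean)
  n <- 3; a <- 2; b <- 2
  ss_a <- b * n * sum((a_means - ybar)^2)
  ss_b <- a * n * sum((b_means - ybar)^2)
  ss_cells <- n * sum((cell_means - ybar)^2)
  ss_ab <- ss_cells - ss_a - ss_b
  ss_e <- sum((y - cell_means[interaction(d$site, d$season)])^2)
  df_e <- a * b * (n - 1)
  f_oracle <- c(ss_a / 1, ss_b / 1, ss_ab / 1) / (ss_e / df_e)

  got <- res$anova
  expect_equal(got$F[match(c("site", "season", "site:season"), got$term)],
               f_oracle, tolerance = 1e-10)
  expect_true(all(c("statistic", "p") %in% names(res$ks)))
  expect_true(is.finite(res$levene$F))
})

test_that("equal cell means give near-zero F and no post hoc stage", {
  d <- expand.grid(site = c("EXP", "SHE"), season = c("NoUp", "Up"), rep = 1:4)
  # same mean in every cell, with asymmetric within-cell spread (keeps the
  # Levene response non-degenerate)
  d$prop <- 0.3 + c(-0.012, -0.004, 0.004, 0.012)[d$rep]
  res <- classic_cover_tests(d)
  expect_true(all(res$anova$F < 1e-20 | res$anova$p > 0.9))
  expect_null(res$pairwise)
  expect_error(classic_cover_tests(d[1:5, ]), ">= 2")
})

test_that("significant interaction triggers Bonferroni-adjusted cell comparisons", {
  d <- expand.grid(site = c("EXP", "SHE"), season = c("NoUp", "Up"), rep = 1:5)
  set.seed(4)
  mu <- ifelse(d$site == "EXP" & d$season == "Up", 0.8, 0.2)
  d$prop <- mu + rnorm(nrow(d), 0, 0.02)
  res <- classic_cover_tests(d)
  expect_false(is.null(res$pairwise))
  expect_equal(nrow(res$pairwise), choose(4, 2))
  expect_equal(res$pairwise$p_adj,
               pmin(1, res$pairwise$p_raw * choose(4, 2)))
})

test_that("post hoc cell comparisons match the pooled-variance t oracle", {
  d <- expand.grid(site = c("EXP", "SHE"), season = c("NoUp", "Up"), rep = 1:5)
  set.seed(9)
  mu <- ifelse(d$site == "EXP" & d$season == "Up", 0.8, 0.2)
  d$prop <- mu + rnorm(nrow(d), 0, 0.02)
  res <- classic_cover_tests(d)
  g1 <- d$prop[d$site == "EXP" & d$season == "NoUp"]
  g2 <- d$prop[d$site == "SHE" & d$season == "NoUp"]
  # hand-computed pooled-variance two-sample t and its p-value
  sp2 <- (sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)) / (length(g1) + length(g2) - 2)
  t_stat <- (mean(g1) - mean(g2)) / sqrt(sp2 * (1 / length(g1) + 1 / length(g2)))
  p_hand <- 2 * stats::pt(-abs(t_stat), df = length(g1) + length(g2) - 2)
  row <- res$pairwise[res$pairwise$pair == "EXP.NoUp vs SHE.NoUp", ]
  expect_equal(row$p_raw, p_hand, tolerance = 1e-12)
  expect_equal(row$diff, mean(g1) - mean(g2), tolerance = 1e-12)
})
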