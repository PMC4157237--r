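# Synthetic input generator

test_that("identical seed and scenario give byte-identical tables", {
  sc <- small_scenario()
  t1 <- simulate_inputs(sc, seed = 11, n_logger = 50)
  t2 <- simulate_inputs(sc, seed = 11, n_logger = 50)
  expect_identical(t1, t2)
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  f1 <- write_simulation(t1, d1)
  f2 <- write_simulation(t2, d2)
  for (i in seq_along(f1)) {
    expect_identical(readBin(f1[i], "raw", file.size(f1[i])),
                     readBin(f2[i], "raw", file.size(f2[i])))
  }
})

test_that("generated tables satisfy their type invariants", {
  t <- simulate_inputs(small_scenario(), seed = 2, n_logger = 50)
  inc <- t$incubations
  expect_true(all(inc$duration_h > 0))
  expect_true(all(inc$volume_l > 0))
  expect_true(all(inc$area2d_cm2 > 0))
  expect_true(all(inc$o2_start_mg_l >= 0))
  expect_true(all(inc$group %in% flux_groups()))
  expect_true(all(t$blanks$duration_h > 0))
  expect_true(all(t$rugosity$chain_m >= t$rugosity$linear_m))
  expect_true(all(t$surface_pairs$area3d_cm2 >= t$surface_pairs$area2d_cm2))
  # light and dark phases are paired per specimen
  expect_identical(sort(inc$sample_id[inc$phase == "light"]),
                   sort(inc$sample_id[inc$phase == "dark"]))
})

test_that("unknown cell keys are a configuration error", {
  sc <- small_scenario()
  bad <- data.frame(group = "kelp", site = "EXP", season = "NoUp")
  expect_error(gen_incubations(sc, cells = bad), "unknown")
  expect_error(gen_transects(sc, "ATLANTIS", "NoUp", 1), "no cover probabilities")
  expect_error(gen_rugosity(sc, "ATLANTIS", 3), "no rugosity")
  expect_error(gen_logger(sc, "monsoon", 10), "no logger")
})

test_that("zero-SD scenario round-trips every flux exactly through the pipeline", {
  sc <- flat_scenario(light_mean = 5, dark_mean = -1)
  g <- gen_incubations(sc, seed = 7)
  fl <- compute_fluxes(g$incubations, g$blanks, sc$conversion_factors)
  expect_equal(fl$light_flux, rep(5, nrow(fl)), tolerance = 1e-10)
  expect_equal(fl$dark_flux, rep(-1, nrow(fl)), tolerance = 1e-10)
})

test_that("coral non-upwelling cell recovers a net production near 16", {
  sc <- default_scenario(n_replicates = 200)
  cells <- data.frame(group = c("coral_montastraea", "coral_diploria"),
                      site = "EXP", season = "NoUp")
  g <- gen_incubations(sc, cells = cells, seed = 5)
  fl <- compute_fluxes(g$incubations, g$blanks, scenario_s_factors(sc))
  # scenario mean 16, sd 4: sample mean of 400 specimens within 2 SE
  se <- 4 / sqrt(nrow(fl))
  expect_lt(abs(mean(fl$p_n) - 16), 2 * se)
})

test_that("transects have 101 points and match their cover probabilities", {
  sc <- small_scenario()
  tr <- gen_transects(sc, "EXP", "NoUp", 4, seed = 3)
  expect_identical(as.integer(table(tr$transect_id)), rep(101L, 4))
  expect_identical(unique(tr$point_index), 0:100)

  sc1 <- sc
  sc1$cover_probs <- data.frame(site = "EXP", season = "NoUp",
                                category = "coral", prob = 1)
  tr1 <- gen_transects(sc1, "EXP", "NoUp", 2, seed = 3)
  expect_true(all(tr1$label == "coral"))

  # pooled coral frequency over many transects near the configured 0.41
  tr_many <- gen_transects(sc, "EXP", "NoUp", 500, seed = 9)
  p_hat <- mean(tr_many$label == "coral")
  se <- sqrt(0.41 * 0.59 / (500 * 101))
  expect_lt(abs(p_hat - 0.41), 2 * se)

  sc_bad <- sc
  sc_bad$cover_probs$prob[1] <- sc_bad$cover_probs$prob[1] + 0.001
  expect_error(gen_transects(sc_bad, "EXP", "NoUp", 1), "sum to 1")
})

test_that("rugosity draws respect the chain geometry and truncation at 1", {
  sc <- small_scenario()
  sc$rugosity$sd <- 0
  r_exp <- gen_rugosity(sc, "EXP", 5)
  expect_equal(r_exp$chain_m, rep(13.2, 5))
  sc$rugosity$mean <- c(1, 1)
  r_flat <- gen_rugosity(sc, "SHE", 5)
  expect_equal(r_flat$chain_m, r_flat$linear_m)
  # heavy noise never produces a ratio below 1
  sc2 <- small_scenario()
  sc2$rugosity$mean <- c(1.01, 1.01)
  sc2$rugosity$sd <- c(0.5, 0.5)
  r_noisy <- gen_rugosity(sc2, "EXP", 1e4, seed = 13)
  expect_true(all(r_noisy$chain_m / r_noisy$linear_m >= 1))
})

test_that("logger series convert to the configured PAR regimes", {
  sc <- small_scenario()
  lg <- gen_logger(sc, "NoUp", 5000, seed = 21)
  par <- lux_to_par(lg$light_lx, k = sc$lux_to_par_k)
  se <- 47 / sqrt(5000)
  expect_lt(abs(mean(par) - 146), 2 * se)
  expect_equal(diff(lg$t_min)[1], 2)

  lg_up <- gen_logger(sc, "Up", 5000, seed = 22)
  expect_gt(mean(lux_to_par(lg_up$light_lx, k = sc$lux_to_par_k)), mean(par))

  sc0 <- sc
  sc0$logger$temp_sd <- 0
  sc0$logger$light_lx_sd <- 0
  lg0 <- gen_logger(sc0, "NoUp", 10)
  expect_equal(stats::sd(lg0$temp_c), 0)
  expect_equal(stats::sd(lg0$light_lx), 0)
})

test_that("surface pairs reproduce the configured conversion factors", {
  sc <- small_scenario()
  sc$conversion_factors$sd <- 0
  dip <- gen_surface_pairs(sc, "coral_diploria", 6, seed = 4)
  expect_equal(dip$area3d_cm2 / dip$area2d_cm2, rep(2.28, 6))
  ma <- gen_surface_pairs(sc, "macroalgae", 6, seed = 4)
  expect_equal(ma$area3d_cm2 / ma$area2d_cm2, rep(4.29, 6))
  sc$conversion_factors$mean <- rep(1, nrow(sc$conversion_factors))
  flat <- gen_surface_pairs(sc, "turf", 6, seed = 4)
  expect_equal(flat$area3d_cm2, flat$area2d_cm2)
})

test_that("scenario validation rejects broken configurations", {
  sc <- small_scenario()
  sc$cover_probs$prob[1] <- sc$cover_probs$prob[1] + 0.5
  expect_error(validate_scenario(sc), "sum to 1")
  sc2 <- small_scenario()
  sc2$conversion_factors$mean[1] <- 0.8
  expect_error(validate_scenario(sc2), ">= 1")
  sc3 <- small_scenario()
  sc3$flux_params$sd[1] <- -1
  expect_error(validate_scenario(sc3), "sd")
})
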