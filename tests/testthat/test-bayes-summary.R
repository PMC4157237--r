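# Power transform, model averaging, HPD intervals, pMCMC

test_that("power transform follows Taylor's law slope", {
  # variance independent of the mean (slope exactly 0): identity transform
  y <- c(1 - 1, 1 + 1, 4 - 1, 4 + 1, 9 - 1, 9 + 1, 16 - 1, 16 + 1)
  cell <- rep(c("a", "b", "c", "d"), each = 2)
  pt <- power_transform(y, cell)
  expect_equal(pt$slope, 0, tolerance = 1e-12)
  expect_equal(pt$lambda, 1)
  expect_equal(pt$branch, "power")
  expect_equal(pt$values, y)

  # variance proportional to mean^2 (slope exactly 2): log branch
  m <- c(1, 3, 9, 27)
  y2 <- as.vector(t(outer(m, c(0.9, 1.1))))        # cell sd proportional to mean
  cell2 <- rep(c("a", "b", "c", "d"), each = 2)
  pt2 <- power_transform(y2, cell2)
  expect_equal(pt2$slope, 2, tolerance = 1e-10)
  expect_equal(pt2$branch, "log")
  expect_equal(pt2$values, sign(y2) * log1p(abs(y2)))

  # negative values keep their sign
  pt3 <- power_transform(c(-8, -2, 1, 3, 5, 9), rep(c("a", "b", "c"), each = 2))
  expect_equal(sign(pt3$values), sign(c(-8, -2, 1, 3, 5, 9)))

  expect_error(power_transform(rnorm(4), rep(c("a", "b"), each = 2)), ">= 3 cells")
  expect_error(power_transform(rep(0, 8), rep(c("a", "b", "c", "d"), each = 2)),
               "zero")
})

test_that("power transform stabilizes a quadratic mean-variance relation", {
  # cell means well above 1, where the sign-preserving log1p branch acts
  # like a log and can undo a var ~ mean^2 relation
  set.seed(14)
  means <- exp(seq(log(10), log(200), length.out = 10))
  y <- unlist(lapply(means, function(m) m * exp(rnorm(200, 0, 0.3))))
  cell <- rep(paste0("c", 1:10), each = 200)
  pt <- power_transform(y, cell)
  # post-transform Taylor slope should collapse towards 0
  tm <- tapply(pt$values, cell, mean)
  tv <- tapply(pt$values, cell, stats::var)
  slope_after <- unname(stats::coef(stats::lm(log(tv) ~ log(abs(tm))))[2])
  expect_lt(abs(slope_after), 0.2)
})

test_that("DIC weights and the candidate window follow the exp(-delta/2) rule", {
  coefs <- list(c("(Intercept)" = 1), c("(Intercept)" = 3, x = 2))
  # single candidate
  ma1 <- model_average(c(10, 20), coefs)
  expect_equal(ma1$weights, c(1, 0))
  expect_equal(ma1$coefficients, c("(Intercept)" = 1, x = 0))
  # dDIC = {0, 2}: weights exp(0), exp(-1) normalized
  ma2 <- model_average(c(100, 102), coefs)
  expect_equal(unname(ma2$weights), c(0.731, 0.269), tolerance = 5e-4)
  w <- exp(0) / (exp(0) + exp(-1))
  expect_equal(unname(ma2$coefficients["(Intercept)"]), w * 1 + (1 - w) * 3)
  expect_equal(unname(ma2$coefficients["x"]), (1 - w) * 2)
  # dDIC = {0, 5}: second model excluded
  ma3 <- model_average(c(100, 105), coefs)
  expect_equal(ma3$weights, c(1, 0))
  expect_equal(ma3$candidates, 1L)
})

test_that("stacked draws pool candidate models on the union space", {
  draws <- list(matrix(1, 100, 1, dimnames = list(NULL, "(Intercept)")),
                matrix(2, 100, 2, dimnames = list(NULL, c("(Intercept)", "x"))))
  coefs <- list(c("(Intercept)" = 1), c("(Intercept)" = 2, x = 2))
  ma <- model_average(c(100, 102), coefs, draws = draws)
  expect_equal(colnames(ma$stacked_draws), c("(Intercept)", "x"))
  w1 <- exp(0) / (exp(0) + exp(-1))
  expect_equal(nrow(ma$stacked_draws), round(w1 * 100) + round((1 - w1) * 100))
  # absent coefficients enter as zero
  expect_true(all(ma$stacked_draws[ma$stacked_draws[, 1] == 1, "x"] == 0))
})

test_that("HPD is the shortest interval with stated tie-breaking", {
  expect_equal(unname(hpd(rep(2.5, 25))), c(2.5, 2.5))
  expect_equal(unname(hpd(1:1000)), c(1, 950))
  set.seed(6)
  z <- rnorm(1e5)
  h <- hpd(z)
  expect_lt(abs(h[["lower"]] + 1.959964), 0.05)
  expect_lt(abs(h[["upper"]] - 1.959964), 0.05)
  expect_error(hpd(rnorm(10)), ">= 20")
})

test_that("HPD matches the brute-force scan and beats equal tails", {
  set.seed(61)
  for (i in 1:20) {
    s <- rgamma(500, shape = 2, rate = 1)
    h <- hpd(s, 0.9)
    expect_equal(unname(h), hpd_bruteforce(s, 0.9), tolerance = 1e-12)
    eq <- unname(stats::quantile(s, c(0.05, 0.95)))
    expect_lte(h[["upper"]] - h[["lower"]], eq[2] - eq[1] + 1e-12)
  }
})

test_that("pMCMC implements the doubled-tail rule with a 2/n floor", {
  one_col <- function(d) matrix(d, ncol = 1, dimnames = list(NULL, "b"))
  cmp <- pairwise_compare(one_col(abs(rnorm(1000)) + 0.01), list(p = c(b = 1)))
  expect_equal(cmp$pmcmc, 0.002)   # all positive: floored at 2/1000
  expect_equal(cmp$stars, "**")
  set.seed(3)
  sym <- rnorm(2000)
  cmp2 <- pairwise_compare(one_col(sym), list(p = c(b = 1)))
  expect_gt(cmp2$pmcmc, 0.9)
  d3 <- c(rep(-1, 300), rep(1, 700)) + rnorm(1000, 0, 1e-6)
  cmp3 <- pairwise_compare(one_col(d3), list(p = c(b = 1)))
  expect_equal(cmp3$pmcmc, 0.6)    # 2 * 0.3
  expect_equal(cmp3$stars, "")
  expect_error(pairwise_compare(one_col(sym), list(p = c(qqq = 1))), "unknown")
})

test_that("HPD-excludes-zero and pMCMC decisions are consistent", {
  # if zero lies outside the shortest 95% window, at most n - ceiling(0.95 n)
  # draws sit beyond it, so pMCMC <= 2 (n - m)/n exactly; the familiar
  # "pMCMC < 0.05" reading holds up to window-placement noise
  set.seed(77)
  n <- 600
  m <- ceiling(0.95 * n)
  ps <- c()
  for (i in 1:100) {
    d <- rnorm(n, mean = runif(1, -0.3, 0.3), sd = 0.1)
    h <- hpd(d, 0.95)
    if (h[["lower"]] > 0 || h[["upper"]] < 0) {
      p <- pairwise_compare(matrix(d, ncol = 1, dimnames = list(NULL, "b")),
                            list(x = c(b = 1)))$pmcmc
      expect_lte(p, 2 * (n - m) / n)
      ps <- c(ps, p)
    }
  }
  expect_gt(length(ps), 10)
  # and every case sits near the nominal 0.05 level, within the
  # window-placement noise of the shortest-interval search
  expect_true(all(ps < 0.05 + 2 / n + 0.02))
})
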