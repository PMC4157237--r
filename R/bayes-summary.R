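# Posterior summaries: variance-stabilizing transform, DIC model averaging,
# HPD intervals and pairwise posterior comparisons.

#' Variance-stabilizing power transform via Taylor's power law
#'
#' Regresses log cell variance on log |cell mean| over the design cells
#' (Taylor's power law, slope b), then applies the signed power
#' \eqn{y \mapsto sign(y) |y|^\lambda} with \eqn{\lambda = 1 - b/2}. When
#' \eqn{|\lambda| < 0.05} the transform degenerates towards the logarithm and
#' the sign-preserving \code{log1p} branch is used instead:
#' \eqn{y \mapsto sign(y) \log(1 + |y|)}. Signed handling matters because
#' dark-phase sediment fluxes can be negative.
#'
#' @param y numeric response values.
#' @param cell factor (or coercible) of design-cell membership.
#' @param min_cells minimum number of cells with >= 2 replicates required.
#' @return list with \code{values} (transformed y), \code{lambda},
#'   \code{slope} (Taylor b), \code{branch} ("power" or "log").
#' @export
power_transform <- function(y, cell, min_cells = 3) {
  cell <- factor(cell)
  ns <- tapply(y, cell, length)
  usable <- names(ns)[ns >= 2]
  if (length(usable) < min_cells) {
    stop_config("need >= %d cells with >= 2 replicates (have %d)",
                min_cells, length(usable))
  }
  m <- tapply(y, cell, mean)[usable]
  v <- tapply(y, cell, stats::var)[usable]
  if (all(m == 0)) stop_config("all cell means are zero; transform undefined")
  ok <- m != 0 & v > 0
  if (sum(ok) >= 2) {
    slope <- unname(stats::coef(stats::lm(log(v[ok]) ~ log(abs(m[ok]))))[2])
  } else {
    warning("too few informative cells for Taylor regression; assuming slope 0")
    slope <- 0
  }
  lambda <- 1 - slope / 2
  if (abs(lambda) < 0.05) {
    values <- sign(y) * log1p(abs(y))
    branch <- "log"
  } else {
    values <- sign(y) * abs(y)^lambda
    branch <- "power"
  }
  list(values = values, lambda = lambda, slope = slope, branch = branch)
}

#' DIC weights and coefficient averaging over the candidate window
#'
#' Models within a DIC window of the best one (dDIC <= \code{window},
#' default 2) form the candidate set; their weights are
#' \eqn{w_m \propto \exp(-\Delta DIC_m / 2)} normalized over the set.
#' Posterior-mean coefficients are averaged on the union coefficient space
#' with coefficients absent from a model treated as 0. If draw matrices are
#' supplied, a DIC-weight-stacked draw matrix on the union space is also
#' returned (each model contributes its first \code{round(w * n)} retained
#' draws, zero-padded) for posterior contrast inference under model
#' uncertainty.
#'
#' @param dic_values numeric DICs, one per model.
#' @param coefs list of named posterior-mean coefficient vectors.
#' @param draws optional list of draw matrices with named columns.
#' @param window DIC window (inclusive).
#' @return list with \code{candidates} (indices), \code{delta} (all models),
#'   \code{weights} (all models; 0 outside the window), \code{coefficients}
#'   (averaged, union space), \code{stacked_draws} (matrix or NULL).
#' @export
model_average <- function(dic_values, coefs, draws = NULL, window = 2) {
  if (length(dic_values) < 1) stop_config("need at least one model")
  if (length(coefs) != length(dic_values)) {
    stop_config("coefs must align with dic_values")
  }
  delta <- dic_values - min(dic_values)
  cand <- which(delta <= window)
  w <- numeric(length(dic_values))
  w[cand] <- exp(-delta[cand] / 2)
  w <- w / sum(w)
  union_names <- unique(unlist(lapply(coefs, names)))
  pad <- function(v) {
    out <- stats::setNames(numeric(length(union_names)), union_names)
    out[names(v)] <- v
    out
  }
  avg <- Reduce(`+`, Map(function(v, wi) pad(v) * wi, coefs, as.list(w)))
  stacked <- NULL
  if (!is.null(draws)) {
    n_total <- nrow(draws[[cand[1]]])
    blocks <- lapply(cand, function(i) {
      m <- max(1L, round(w[i] * n_total))
      D <- draws[[i]][seq_len(min(m, nrow(draws[[i]]))), , drop = FALSE]
      out <- matrix(0, nrow(D), length(union_names),
                    dimnames = list(NULL, union_names))
      out[, colnames(D)] <- D
      out
    })
    stacked <- do.call(rbind, blocks)
  }
  list(candidates = cand, delta = delta, weights = w, coefficients = avg,
       stacked_draws = stacked)
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval over the sorted samples containing
#' \code{ceiling(level * n)} of them; ties are broken towards the smallest
#' lower endpoint. For unimodal posteriors this is the HPD interval; it is
#' never longer than the equal-tailed interval.
#'
#' @param samples numeric vector (>= 20 values).
#' @param level coverage level.
#' @return named numeric vector c(lower, upper).
#' @export
hpd <- function(samples, level = 0.95) {
  n <- length(samples)
  if (n < 20) stop_config("need >= 20 samples for an HPD interval")
  s <- sort(samples)
  m <- ceiling(level * n)
  widths <- s[m:n] - s[1:(n - m + 1)]
  i <- which.min(widths)   # first minimum = smallest lower endpoint
  c(lower = s[i], upper = s[i + m - 1])
}

# posterior two-tailed evidence for a contrast differing from zero,
# floored at the Monte-Carlo resolution 2/n
pmcmc_value <- function(d) {
  n <- length(d)
  p <- 2 * min(mean(d > 0), mean(d < 0))
  min(1, max(p, 2 / n))
}

significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' Posterior pairwise comparisons
#'
#' For each contrast (a vector on the coefficient space, typically the
#' difference of two cell design rows), computes the posterior of the
#' difference, its posterior mean, 95\% HPD, pMCMC (twice the smaller tail
#' probability, floored at 2/n draws) and significance stars at
#' 0.05 / 0.01 / 0.001.
#'
#' @param draws matrix of posterior draws (rows) by coefficients (named
#'   columns), e.g. the stacked draws from \code{\link{model_average}}.
#' @param contrasts named list of numeric contrast vectors; names may be a
#'   subset of the draw columns (missing coefficients contribute 0).
#' @param level HPD level.
#' @return data.frame: pair, mean_diff, hpd_lo, hpd_hi, pmcmc, stars.
#' @export
pairwise_compare <- function(draws, contrasts, level = 0.95) {
  out <- lapply(names(contrasts), function(nm) {
    x <- contrasts[[nm]]
    if (is.null(names(x))) {
      if (length(x) != ncol(draws)) {
        stop_config("unnamed contrast '%s' must have length ncol(draws)", nm)
      }
      d <- as.numeric(draws %*% x)
    } else {
      unknown <- setdiff(names(x), colnames(draws))
      if (length(unknown) > 0) {
        stop_config("contrast '%s' references unknown coefficient(s): %s",
                    nm, paste(unknown, collapse = ", "))
      }
      d <- as.numeric(draws[, names(x), drop = FALSE] %*% x)
    }
    h <- hpd(d, level)
    p <- pmcmc_value(d)
    data.frame(pair = nm, mean_diff = mean(d), hpd_lo = h[["lower"]],
               hpd_hi = h[["upper"]], pmcmc = p, stars = significance_stars(p),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
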