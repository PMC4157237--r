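# Conjugate Gibbs sampler for the Gaussian linear model and DIC.

#' MCMC chain settings
#'
#' Two built-in profiles: \code{"full"} (650,000 iterations, 50,000 burn-in,
#' thinning 5 -> 120,000 retained draws, the production profile) and
#' \code{"test"} (6,500 / 500 / 5 -> 1,200 retained, for fast test runs).
#' Any setting can be overridden.
#'
#' @param profile \code{"test"} or \code{"full"}.
#' @param n_iter,burnin,thin optional overrides.
#' @return list with n_iter, burnin, thin, n_keep.
#' @export
chain_profile <- function(profile = c("test", "full"), n_iter = NULL,
                          burnin = NULL, thin = NULL) {
  profile <- match.arg(profile)
  base <- if (profile == "full") list(n_iter = 650000L, burnin = 50000L, thin = 5L)
          else list(n_iter = 6500L, burnin = 500L, thin = 5L)
  out <- list(n_iter = as.integer(n_iter %||% base$n_iter),
              burnin = as.integer(burnin %||% base$burnin),
              thin = as.integer(thin %||% base$thin))
  if (out$burnin >= out$n_iter) stop_config("burn-in must be < total iterations")
  if ((out$n_iter - out$burnin) %% out$thin != 0L) {
    stop_config("(n_iter - burnin) must be divisible by thin")
  }
  out$n_keep <- (out$n_iter - out$burnin) %/% out$thin
  out
}

#' Gibbs sampler for the Gaussian linear model
#'
#' Conjugate blocked Gibbs: coefficients given the residual variance are
#' multivariate normal, the variance given the coefficients is
#' inverse-gamma. Priors are weakly informative: coefficients
#' Normal(0, prior_var * I) with prior_var = 1e8, variance
#' InverseGamma(0.001, 0.001). Because the coefficient prior is isotropic,
#' the sampler works in the SVD-rotated coordinate system of the design
#' matrix, where the full conditional precision is diagonal; draws are mapped
#' back to the original coefficient space once at the end. Fully
#' deterministic under the seed.
#'
#' @param y numeric response (finite).
#' @param X design matrix from \code{\link{design_matrix}} (full column
#'   rank).
#' @param chain settings from \code{\link{chain_profile}}.
#' @param seed integer seed.
#' @param prior_var prior variance of coefficients.
#' @param prior_shape,prior_rate inverse-gamma prior on the residual
#'   variance.
#' @return object of class \code{posterior_draws}: list with \code{beta}
#'   (retained draws x coefficients, named columns), \code{sigma2} (retained
#'   variance draws), \code{chain}, \code{seed}.
#' @export
gibbs_fit <- function(y, X, chain = chain_profile("test"), seed = 1L,
                      prior_var = 1e8, prior_shape = 0.001, prior_rate = 0.001) {
  if (any(!is.finite(y))) stop_config("response contains non-finite values")
  if (length(y) != nrow(X)) stop_config("length(y) must equal nrow(X)")
  set.seed(as.integer(seed))
  n <- length(y)
  p <- ncol(X)
  sv <- svd(X)
  if (min(sv$d) < max(sv$d) * 1e-10) {
    stop_config("design matrix is numerically rank deficient")
  }
  d <- sv$d
  z <- as.numeric(crossprod(sv$u, y))   # length p
  yty <- sum(y^2)
  W <- matrix(0, chain$n_keep, p)
  s2 <- numeric(chain$n_keep)
  sigma2 <- stats::var(y)
  if (!is.finite(sigma2) || sigma2 <= 0) sigma2 <- 1
  keep <- 0L
  for (it in seq_len(chain$n_iter)) {
    prec <- d^2 / sigma2 + 1 / prior_var
    w_mean <- (d * z / sigma2) / prec
    w <- w_mean + stats::rnorm(p) / sqrt(prec)
    ssr <- yty - 2 * sum(w * d * z) + sum((d * w)^2)
    sigma2 <- 1 / stats::rgamma(1, prior_shape + n / 2, prior_rate + ssr / 2)
    if (it > chain$burnin && (it - chain$burnin) %% chain$thin == 0L) {
      keep <- keep + 1L
      W[keep, ] <- w
      s2[keep] <- sigma2
    }
  }
  beta <- W %*% t(sv$v)
  colnames(beta) <- colnames(X)
  structure(list(beta = beta, sigma2 = s2, chain = chain, seed = as.integer(seed)),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat("posterior_draws:", nrow(x$beta), "retained draws x", ncol(x$beta),
      "coefficients (seed", x$seed, ")\n")
  invisible(x)
}

#' Deviance information criterion for a fitted Gaussian linear model
#'
#' Deviance is minus twice the Gaussian log-likelihood. \code{Dbar} is the
#' posterior mean deviance over the retained draws; \code{Dhat} the deviance
#' at the posterior means of the coefficients and the residual variance;
#' \code{pD = Dbar - Dhat} is the effective number of parameters and
#' \code{DIC = Dbar + pD = 2 Dbar - Dhat}. A negative pD (a sign of a poorly
#' behaved posterior) is reported with a warning, never hidden.
#'
#' @param draws a \code{posterior_draws} object.
#' @param y,X the data the model was fitted to.
#' @return list with Dbar, Dhat, pD, DIC.
#' @export
dic <- function(draws, y, X) {
  B <- draws$beta
  if (nrow(B) == 0) stop_config("no retained draws")
  n <- length(y)
  XtX <- crossprod(X)
  Xty <- as.numeric(crossprod(X, y))
  yty <- sum(y^2)
  ssr <- yty - 2 * as.numeric(B %*% Xty) + rowSums((B %*% XtX) * B)
  dev <- n * log(2 * pi * draws$sigma2) + ssr / draws$sigma2
  dbar <- mean(dev)
  beta_hat <- colMeans(B)
  s2_hat <- mean(draws$sigma2)
  ssr_hat <- yty - 2 * sum(beta_hat * Xty) + sum(beta_hat * (XtX %*% beta_hat))
  dhat <- n * log(2 * pi * s2_hat) + ssr_hat / s2_hat
  pd <- dbar - dhat
  if (pd < 0) warning(sprintf("negative pD (%.3f): posterior may be poorly behaved", pd))
  list(Dbar = dbar, Dhat = dhat, pD = pd, DIC = dbar + pd)
}
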