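# High-level inference: fit all candidate models to a production response,
# average by DIC weight, and compare design cells on the posterior.

#' Fit the candidate model set to a production response
#'
#' The statistical engine of the pipeline. The response (an individual flux
#' or a seafloor contribution) is variance-stabilized by
#' \code{\link{power_transform}} over the design cells, all hierarchical
#' candidate models over the factors G (benthic group), S (site) and
#' W (season) -- 19 models for three factors -- are fitted by
#' \code{\link{gibbs_fit}}, ranked by \code{\link{dic}}, and averaged with
#' \code{\link{model_average}}. Inference stays on the transformed scale.
#'
#' @param data data.frame of observations.
#' @param response name of the response column.
#' @param factors named character vector mapping the model factors to data
#'   columns; default \code{c(G = "group", S = "site", W = "season")}.
#' @param chain settings from \code{\link{chain_profile}}.
#' @param seed integer seed; model m is fitted with seed \code{seed + m}.
#' @param transform apply the power transform (TRUE) or fit the raw response.
#' @param window DIC window for the candidate set.
#' @return object of class \code{reef_fit}: list with \code{model_table}
#'   (model, Dbar, pD, DIC, delta, weight), \code{average} (from
#'   \code{\link{model_average}}), \code{transform}, \code{levels} (factor
#'   levels), \code{response}, \code{chain}, \code{seed}.
#' @export
fit_production_models <- function(data, response,
                                  factors = c(G = "group", S = "site", W = "season"),
                                  chain = chain_profile("test"), seed = 1L,
                                  transform = TRUE, window = 2) {
  if (!response %in% names(data)) stop_config("response column '%s' not found", response)
  d <- data.frame(lapply(factors, function(col) {
    if (!col %in% names(data)) stop_config("factor column '%s' not found", col)
    factor(data[[col]])
  }))
  names(d) <- names(factors)
  y_raw <- data[[response]]
  cell <- interaction(d, drop = TRUE)
  if (transform) {
    pt <- power_transform(y_raw, cell)
  } else {
    pt <- list(values = y_raw, lambda = 1, slope = NA_real_, branch = "identity")
  }
  y <- pt$values
  models <- enumerate_models(names(factors))
  fits <- vector("list", length(models))
  dics <- numeric(length(models))
  coefs <- vector("list", length(models))
  draws <- vector("list", length(models))
  info <- vector("list", length(models))
  for (m in seq_along(models)) {
    X <- design_matrix(d, models[[m]])
    fit <- gibbs_fit(y, X, chain = chain, seed = seed + m)
    ic <- dic(fit, y, X)
    fits[[m]] <- fit
    dics[m] <- ic$DIC
    coefs[[m]] <- colMeans(fit$beta)
    draws[[m]] <- fit$beta
    info[[m]] <- data.frame(
      model = if (length(models[[m]]) == 0) "1" else paste(models[[m]], collapse = " + "),
      Dbar = ic$Dbar, pD = ic$pD, DIC = ic$DIC, stringsAsFactors = FALSE)
  }
  avg <- model_average(dics, coefs, draws = draws, window = window)
  model_table <- do.call(rbind, info)
  model_table$delta <- avg$delta
  model_table$weight <- avg$weights
  model_table <- model_table[order(model_table$DIC), ]
  rownames(model_table) <- NULL
  structure(list(model_table = model_table, average = avg, transform = pt,
                 levels = lapply(d, levels), response = response,
                 factors = factors, chain = chain, seed = as.integer(seed)),
            class = "reef_fit")
}

#' @export
print.reef_fit <- function(x, ...) {
  cat("reef_fit for response '", x$response, "' (", x$transform$branch,
      " transform, lambda = ", signif(x$transform$lambda, 3), ")\n", sep = "")
  cat("candidate models (dDIC <= 2):",
      sum(x$model_table$weight > 0), "of", nrow(x$model_table), "\n")
  print(utils::head(x$model_table, 5))
  invisible(x)
}

# design rows for every factor-level combination, in the union (full-model)
# coefficient space of the fit
cell_design <- function(fit) {
  grid <- expand.grid(fit$levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = TRUE)
  full_terms <- enumerate_models(names(fit$levels))
  full <- full_terms[[which.max(lengths(full_terms))]]
  X <- design_matrix(grid, full)
  rownames(X) <- apply(grid, 1, paste, collapse = "_")
  list(grid = grid, X = X)
}

#' Posterior comparisons between design cells
#'
#' Builds the posterior of each requested cell-mean difference from the
#' DIC-weight-stacked draws of a \code{\link{fit_production_models}} fit and
#' summarizes it with \code{\link{pairwise_compare}}. Differences are on the
#' transformed response scale.
#'
#' @param fit a \code{reef_fit}.
#' @param pairs optional 2-column character matrix (or data.frame) of cell
#'   labels (\code{"G_S_W"} with the fit's factor levels); default: all pairs
#'   of observed-level cells.
#' @param level HPD level.
#' @return data.frame from \code{\link{pairwise_compare}}.
#' @export
compare_cells <- function(fit, pairs = NULL, level = 0.95) {
  cd <- cell_design(fit)
  cells <- rownames(cd$X)
  if (is.null(pairs)) {
    cmb <- utils::combn(cells, 2)
    pairs <- cbind(cmb[1, ], cmb[2, ])
  } else {
    pairs <- as.matrix(pairs)
    unknown <- setdiff(unique(as.vector(pairs)), cells)
    if (length(unknown) > 0) {
      stop_config("unknown cell(s): %s (expected G_S_W labels like '%s')",
                  paste(unknown, collapse = ", "), cells[1])
    }
  }
  contrasts <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- cd$X[pairs[i, 1], ] - cd$X[pairs[i, 2], ]
    stats::setNames(as.numeric(x), colnames(cd$X))
  })
  names(contrasts) <- paste(pairs[, 1], "-", pairs[, 2])
  pairwise_compare(fit$average$stacked_draws, contrasts, level = level)
}

#' Posterior cell means of a fitted model set
#'
#' Cell means on the transformed scale: posterior mean and HPD of each
#' design cell under the DIC-weight-stacked posterior.
#'
#' @param fit a \code{reef_fit}.
#' @param level HPD level.
#' @return data.frame: one row per cell with the factor levels, mean, hpd_lo,
#'   hpd_hi.
#' @export
cell_means <- function(fit, level = 0.95) {
  cd <- cell_design(fit)
  draws <- fit$average$stacked_draws
  missing <- setdiff(colnames(cd$X), colnames(draws))
  if (length(missing) > 0) {
    stop_config("stacked draws lack coefficient(s): %s", paste(missing, collapse = ", "))
  }
  # align union-space draw columns with the full-model design columns
  D <- draws[, colnames(cd$X), drop = FALSE] %*% t(cd$X)
  out <- cd$grid
  out$mean <- colMeans(D)
  hp <- apply(D, 2, hpd, level = level)
  out$hpd_lo <- hp["lower", ]
  out$hpd_hi <- hp["upper", ]
  out
}
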