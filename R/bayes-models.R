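# Candidate-model enumeration and design matrices for the Gaussian GLMs.

#' Enumerate hierarchical candidate models
#'
#' All term sets over the given factors (main effects and interactions of any
#' order) that respect marginality: an interaction may only appear together
#' with all its lower-order constituent terms. The intercept-only model (an
#' empty term set) is always included. For k factors the count is the number
#' of downward-closed families of nonempty subsets of a k-set: 2, 5, 19, 167
#' for k = 1..4 -- three factors give the 19 candidate models.
#'
#' @param factors character vector of factor names (1 to 4).
#' @return list of character vectors; each element is one model's term
#'   labels (e.g. \code{c("G", "S", "G:S")}), \code{character(0)} for the
#'   intercept-only model. Terms are ordered by interaction order.
#' @export
enumerate_models <- function(factors) {
  k <- length(factors)
  if (k < 1 || k > 4) stop_config("enumerate_models supports 1 to 4 factors")
  n_terms <- 2L^k - 1L        # nonempty subsets of the factor set
  # required lower-order terms per term: all nonempty proper submasks
  required <- lapply(seq_len(n_terms), function(t) {
    subs <- Filter(function(j) j != t && bitwAnd(j, t) == j, seq_len(n_terms))
    as.integer(subs)
  })
  models <- list()
  for (m in 0:(2L^n_terms - 1L)) {
    present <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n_terms) - 1L)) != 0L)
    ok <- all(vapply(present, function(t) all(required[[t]] %in% present), logical(1)))
    if (ok) models[[length(models) + 1L]] <- present
  }
  term_label <- function(t) paste(factors[which(bitwAnd(t, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)],
                                  collapse = ":")
  order_of <- function(t) sum(bitwAnd(t, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
  lapply(models, function(present) {
    present <- present[order(vapply(present, order_of, numeric(1)), present)]
    vapply(present, term_label, character(1))
  })
}

#' Treatment-coded design matrix for a model term set
#'
#' Builds the reference-level (treatment contrast) design matrix for one
#' candidate model. Columns are ordered intercept, main effects,
#' interactions. Rank deficiency (aliased columns, e.g. from empty factor
#' cells) is an error naming the offending columns rather than a silent drop.
#'
#' @param data data.frame holding the factor columns referenced by
#'   \code{terms}; character columns are converted to factors with their
#'   observed levels.
#' @param terms character vector of term labels (one element of
#'   \code{\link{enumerate_models}}); \code{character(0)} gives the
#'   intercept-only single-column matrix.
#' @return numeric matrix with column names.
#' @export
design_matrix <- function(data, terms) {
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  for (v in vars) {
    if (!v %in% names(data)) stop_config("factor '%s' not found in data", v)
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])
    if (any(table(data[[v]]) == 0)) data[[v]] <- droplevels(data[[v]])
  }
  f <- if (length(terms) == 0) ~1 else stats::reformulate(terms)
  X <- stats::model.matrix(f, data = data,
                           contrasts.arg = lapply(stats::setNames(vars, vars),
                                                  function(v) "contr.treatment"))
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop_config("design matrix is rank deficient; aliased column(s): %s",
                paste(aliased, collapse = ", "))
  }
  X
}
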