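# internal assertion helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop_config("'%s' must be finite and > 0", name)
  }
  invisible(x)
}

assert_nonneg <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0)) {
    stop_config("'%s' must be finite and >= 0", name)
  }
  invisible(x)
}

# molar mass of O2 in g mol^-1, used for mg L^-1 -> mmol L^-1
O2_MOLAR_MASS <- 31.998

#' Benthic functional groups used throughout the pipeline
#'
#' The incubated organism groups. Corals are carried as two genera
#' (brain corals of the Diploria/Pseudodiploria type and boulder corals of
#' the Montastraea/Orbicella type) because their 3D surface geometry, and
#' hence the 2D-to-3D conversion factor, differs strongly; for coverage and
#' upscaling both map to the single "coral" cover category.
#'
#' @return Character vector of group identifiers.
#' @export
flux_groups <- function() {
  c("coral_montastraea", "coral_diploria", "macroalgae", "turf", "cca", "sand")
}

#' Benthic cover categories recorded on transects
#'
#' The closed label vocabulary for line-point-intercept transects: the five
#' autotroph-bearing categories plus an "other" remainder (non-target benthos
#' such as sponges, gorgonians and bare rock). "other" is carried through
#' coverage estimation but excluded from flux upscaling.
#'
#' @return Character vector of category labels.
#' @export
cover_categories <- function() {
  c("coral", "macroalgae", "turf", "cca", "sand", "other")
}

# map an incubation group to its cover category
group_to_category <- function(group) {
  ifelse(group %in% c("coral_montastraea", "coral_diploria"), "coral", group)
}
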