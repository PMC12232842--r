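`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code with a temporary RNG seed
#'
#' Thin wrapper over [withr::with_seed()] so that every stochastic operation
#' in the package is reproducible from an explicit integer seed without
#' disturbing the caller's RNG state.
#'
#' @param seed Integer seed.
#' @param code Code to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed_ <- function(seed, code) {
  withr::with_seed(seed, code)
}

nc_msg <- function(...) {
  if (isTRUE(getOption("nichecomm.verbose", TRUE))) message(...)
  invisible(NULL)
}

stop_nc <- function(...) stop(..., call. = FALSE)

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop_nc(msg)
  invisible(TRUE)
}
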