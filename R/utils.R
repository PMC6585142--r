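#' Round half away from zero
#'
#' Table rendering uses commercial (half-up) rounding so that printed values
#' match the usual one-decimal reporting convention; `base::round()` rounds
#' half to even, which differs on exact .x5 ties.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# isTRUE over possibly-NULL / NA scalars
is_yes <- function(x) !is.null(x) && !is.na(x) && identical(as.character(x), "yes")

`%||%` <- function(a, b) if (is.null(a)) b else a

# scalar tri-state sanity check
check_tristate <- function(x, codes = TRISTATE_OBS, what = "value") {
  x <- as.character(x)
  if (length(x) != 1L || !x %in% codes) {
    stop(sprintf("%s must be one of %s", what, paste(codes, collapse = "/")),
         call. = FALSE)
  }
  x
}

stopifnot_scalar_number <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("%s must be a single finite number", what), call. = FALSE)
  }
  invisible(x)
}
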