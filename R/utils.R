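#' Round half away from zero
#'
#' Base `round()` rounds half to even; clinical tables round half up.
#' Used everywhere a reported size or percentage is formatted.
#'
#' @param x numeric vector
#' @param digits decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

stop_input <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream of independent sub-seeds from one master seed
#'
#' Keeps every simulation reproducible from a single integer while letting
#' replicate loops use distinct streams. All sub-seeds are < 2^31.
#'
#' @param seed master seed (integer)
#' @param n number of sub-seeds
#' @return integer vector of length `n`
#' @export
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}
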