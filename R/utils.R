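#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; published percentage tables in
#' this field conventionally round half up. A tiny epsilon guards against
#' binary representation of values such as 82.05.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + sqrt(.Machine$double.eps)) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistent internal error for generation failures (rejection-sampling cap)
stop_generation_failure <- function(msg, ...) {
  stop(structure(
    class = c("candseq_generation_failure", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}
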