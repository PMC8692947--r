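## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## trapezoidal integral of y over x (x ascending)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}

stop_config <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_config(sprintf("'%s' must be a finite numeric scalar", name))
  if (x < lo || x > hi)
    stop_config(sprintf("'%s' must be in [%s, %s], got %s", name, lo, hi, x))
  invisible(x)
}
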