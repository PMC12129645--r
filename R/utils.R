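# internal helpers shared across modules

stop_param <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# one named RNG stream per call, no global state leaks
with_seed <- function(seed, code) {
  if (is.null(seed) || is.na(seed)) stop_param("a finite integer seed is required")
  withr::with_seed(as.integer(seed), code)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_fraction <- function(x, name, lo = 0, hi = 1, lo_open = FALSE, hi_open = FALSE) {
  if (!is_scalar_number(x)) stop_param(name, " must be a single finite number")
  ok <- (if (lo_open) x > lo else x >= lo) && (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    stop_param(name, " must be in ", if (lo_open) "(" else "[", lo, ", ", hi,
               if (hi_open) ")" else "]", " (got ", format(x), ")")
  }
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  if (!is_scalar_number(x) || x != round(x) || x < min) {
    stop_param(name, " must be an integer >= ", min)
  }
  invisible(as.integer(x))
}
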