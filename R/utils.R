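# internal input checks ------------------------------------------------------

stop_invalid <- function(msg, ...) {
  abort(msg, class = "sacr_invalid_parameter", ...)
}

check_scalar <- function(x, name, positive = TRUE, allow_zero = FALSE,
                         integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_invalid(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive) {
    ok <- if (allow_zero) x >= 0 else x > 0
    if (!ok) {
      stop_invalid(sprintf(
        "`%s` must be %s (got %g).", name,
        if (allow_zero) "non-negative" else "strictly positive", x
      ))
    }
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_invalid(sprintf("`%s` must be a whole number (got %g).", name, x))
  }
  invisible(x)
}

# one-row tibble constructor preserving a subclass
one_row <- function(class, ...) {
  out <- tibble(...)
  class(out) <- c(class, class(out))
  out
}

# pull a single column value out of a one-row data frame
field <- function(x, name) {
  v <- x[[name]]
  if (is.null(v)) stop_invalid(sprintf("missing field `%s`.", name))
  v[[1L]]
}
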