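#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_secshift <- function(msg, class) {
  stop(structure(
    class = c(class, "secshift_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_secshift(sprintf("`%s` must be a single finite number", name),
                  "secshift_parameter_error")
  if (x < lower || x > upper)
    stop_secshift(sprintf("`%s` must be in [%s, %s], got %s",
                          name, lower, upper, x),
                  "secshift_parameter_error")
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != as.integer(x) || x < lower)
    stop_secshift(sprintf("`%s` must be an integer >= %d", name, lower),
                  "secshift_parameter_error")
  invisible(as.integer(x))
}

# Seeds derived from a user seed must stay valid 32-bit integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
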