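# Internal helpers: structured conditions, seeded RNG, misc.

hmg_error <- function(class, message, ...) {
  stop(structure(
    class = c(class, "hmg_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

hmg_warn <- function(class, message, ...) {
  warning(structure(
    class = c(class, "hmg_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

assert_that <- function(cond, class, message) {
  if (!isTRUE(cond)) hmg_error(class, message)
  invisible(TRUE)
}

assert_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    hmg_error("hmg_argument_error",
              sprintf("`%s` must be a single integer >= %d", name, min))
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < 0 || x > 1) {
    hmg_error("hmg_argument_error", sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(as.numeric(x))
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Stable zero-padded ids ("a0003") used to make sort order == numeric order.
pad_id <- function(prefix, i, width = 4L) {
  sprintf("%s%0*d", prefix, width, as.integer(i))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
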