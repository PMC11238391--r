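# Internal helpers shared across modules.

# Deterministically combine a master seed with arbitrary string/integer parts
# into a 32-bit seed. Keeps every derived seed below 2^31 so set.seed() is safe.
derive_seed <- function(...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else as.integer(p)
  }), use.names = FALSE)
  h <- 17
  for (v in parts) {
    h <- (h * 31 + (abs(as.numeric(v)) %% 1000003)) %% 2147483647
  }
  as.integer(h)
}

abort_config <- function(msg, ...) {
  abort(msg, class = "screensim_config_error", ...)
}

abort_validation <- function(msg, ...) {
  abort(msg, class = "screensim_validation_error", ...)
}

abort_infeasible <- function(msg, ...) {
  abort(msg, class = "screensim_infeasible_error", ...)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1,
                           lo_open = FALSE, hi_open = FALSE) {
  ok <- is_scalar_number(x) &&
    (if (lo_open) x > lo else x >= lo) &&
    (if (hi_open) x < hi else x <= hi)
  if (!ok) {
    abort_config(sprintf("`%s` must be a number in %s%s, %s%s (got %s)",
                         name, if (lo_open) "(" else "[", format(lo),
                         format(hi), if (hi_open) ")" else "]",
                         deparse(x)))
  }
  invisible(x)
}
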