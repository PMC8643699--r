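# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
stop_bad <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_num <- function(x, field, positive = FALSE, nonneg = FALSE, finite = TRUE) {
  if (!is.numeric(x)) stop_bad(field, "must be numeric")
  if (finite && any(!is.finite(x))) stop_bad(field, "must be finite")
  if (positive && any(x <= 0)) stop_bad(field, "must be > 0")
  if (nonneg && any(x < 0)) stop_bad(field, "must be >= 0")
  invisible(x)
}

# split one master seed into independent per-purpose seeds (kept < 2^31)
derive_seed <- function(seed, index) {
  (seed * 7919L + index * 104729L) %% 2147483629L
}
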