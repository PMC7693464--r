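# Internal helpers shared across modules.

#' Stop with a classed condition
#'
#' All user-facing errors in the package carry a subclass of
#' `"nirsclench_error"` so callers (and tests) can discriminate failure modes.
#'
#' @param msg message.
#' @param class condition subclass, e.g. `"nc_config_error"`.
#' @noRd
nc_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nirsclench_error", "error")))
}

#' Derive a bounded child seed from a master seed
#'
#' Deterministic integer mixing so each stage/subject gets its own RNG
#' substream while all randomness flows from a single master seed. Result is
#' always within 1 and 2^31 - 2.
#'
#' @param seed master seed (integer-like).
#' @param ... integer offsets identifying the substream.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in offs) {
    s <- (s * 69069 + as.double(o) + 1) %% 2147483647
  }
  as.integer(max(1, s))
}

# round-half-up to integer (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
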