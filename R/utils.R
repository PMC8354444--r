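## small numerical helpers shared across modules

relu <- function(x) pmax(x, 0)

softmax <- function(x) {
  z <- exp(x - max(x))
  z / sum(z)
}

softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(x)))
}

#' Derive a component seed from a master seed
#'
#' A single run seed fans out to named per-component streams (trial
#' generation, parameter initialization, evaluation) so that ablations that
#' share a master seed also share trial sequences. Kept below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param stream character stream name.
#' @return an integer seed.
#' @export
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite values in %s", what))
}
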