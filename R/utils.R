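#' @keywords internal
softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Row-wise softmax for a matrix of logits.
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a * a))
  nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

#' Digest of a parameter set
#'
#' Hash of a model's numeric parameters, used to assert that a frozen
#' backbone is bit-for-bit unchanged by prompt training.
#'
#' @param params A list of numeric vectors/matrices.
#' @return A character scalar hash.
#' @export
param_digest <- function(params) {
  rlang::hash(params)
}

# Deterministic child seed for a named stage, kept within 32-bit range.
derive_seed <- function(master_seed, offset) {
  as.integer((as.numeric(master_seed) * 97L + offset) %% 2147483647)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
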