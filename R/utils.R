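# Shared helpers: seed derivation, config hashing, argument checking.

#' Derive a child seed from a master seed
#'
#' All stochastic entry points accept a single integer seed; sub-tasks
#' (per-patient simulation, per-epoch shuffling, bootstrap resamples) derive
#' their own streams through this function so that runs are reproducible and
#' independent sub-tasks do not share a stream. Kept strictly below 2^31 - 1.
#'
#' @param seed master integer seed.
#' @param k non-negative integer stream index.
#' @return an integer seed.
#' @keywords internal
derive_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 48271 + as.double(k) * 1299721 + 12345) %% 2147483647)
}

#' Hash a configuration object
#'
#' FNV-1a over the serialized object, returned as 8 hex characters. Every
#' file the package writes embeds the hash of the configuration that produced
#' it, so outputs can be traced back to their settings.
#'
#' @param x any R object.
#' @return character scalar, eight hex digits.
#' @export
config_hash <- function(x) {
  bytes <- serialize(x, NULL, version = 2)
  # drop serialization header (R version dependent) before hashing
  bytes <- bytes[-seq_len(14)]
  h <- 2166136261
  for (b in as.integer(bytes)) {
    h <- bitwXor(as.integer(h %% 2147483647), b)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run expr under a local RNG state seeded with `seed`; restores the caller's
# RNG stream afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
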