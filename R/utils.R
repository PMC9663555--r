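## Internal helpers: seed sub-streams, validation, tiny hashing.

# Derive a reproducible 32-bit sub-seed from a master seed and a stream name,
# so stages (world, emissions, ier, vsl, ...) can be re-run independently.
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 7919 + h * 104729) %% (.Machine$integer.max - 1L)) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# djb2-style rolling hash of a character scalar, returned as hex; a run
# identifier for manifests, not a cryptographic digest.
fnv1a <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

# step index (1..T) -> zero-based hour-of-day bin
step_hour <- function(t, steps_per_day) (t - 1L) %% steps_per_day
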