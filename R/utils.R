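# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so library code never perturbs the caller's stream.
#' @noRd
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic integer hash; keeps results in [1, 2^31 - 2] so they are
#' always valid arguments to [set.seed()].
#' @noRd
derive_seed <- function(master, stream) {
  x <- (as.double(master) %% 2147483647) * 7919 + (as.double(stream) %% 2147483647) * 104729
  as.integer(x %% 2147483646) + 1L
}

#' @noRd
stop_cgm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "cgmforecast_error")))
}

#' @noRd
is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1 && is.finite(x) && x >= min && x == as.integer(x)
}

#' @noRd
format_utc <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# Tiny FNV-1a hash over the JSON serialization of a config; used only to stamp
# output artifacts with a provenance digest (not cryptographic).
#' @noRd
config_digest <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = 10, force = TRUE)
  bytes <- utf8ToInt(as.character(s))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
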