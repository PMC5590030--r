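# Local, restorable seeding so simulation functions are reproducible without
# clobbering the caller's RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derived per-stage / per-subject seeds from one root seed; kept below 2^31.
derive_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 104729 * as.numeric(offset)) %% 2147483647L)
}

# round-half-away-from-zero, used for integer CE-voxel counts so fraction
# recovery is exact at sigma = 0
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
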