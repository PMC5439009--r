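# Internal helpers shared across the package.

# Phase grid resolution in ticks: interpretations are searched on the
# sixteenth-note grid (1 tick = 1/96 whole note, so a sixteenth is 6 ticks).
.phase_res <- 6L

`%||%` <- function(x, y) if (is.null(x)) y else x

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
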