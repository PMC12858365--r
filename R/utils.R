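# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Deterministic per-item sub-seed derived from a master seed (kept < 2^31).
derive_seed <- function(seed, i, salt = 0L) {
  as.integer((as.double(seed) * 48271 + i * 7919 + salt * 104729) %% 2147483587)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Voxel-center coordinate arrays (mm) for a grid, origin at the grid corner.
voxel_centers <- function(grid) {
  h <- grid$voxel_size
  lapply(grid$shape, function(n) (seq_len(n) - 0.5) * h)
}

as_vol <- function(x, shape) array(x, dim = shape)
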