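# Internal helpers shared across modules.

# Environment labels follow the "YYYY-HN" / "YYYY-LN" convention.
env_label <- function(year, nitro) paste(year, nitro, sep = "-")

# Harmonic mean of positive counts.
harmonic_mean <- function(x) {
  x <- x[is.finite(x) & x > 0]
  if (length(x) == 0L) return(NA_real_)
  length(x) / sum(1 / x)
}

# Derive a reproducible sub-stream seed from a master seed. Fixed offsets
# keep the sub-streams of the different simulation stages independent of
# one another while remaining valid 32-bit integers.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483563L) + 1L
}

# Run code under a temporary RNG state restored on exit.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Smooth a matrix of row-wise curves on an evenly spaced grid with a
# Gaussian kernel of the given length-scale (grid units).
smooth_rows <- function(mat, grid, length_scale) {
  h <- length_scale / (grid[2] - grid[1])
  half <- min(max(1L, ceiling(3 * h)), ncol(mat) - 1L)
  w <- exp(-0.5 * ((-half:half) / h)^2)
  w <- w / sum(w)
  n <- ncol(mat)
  idx <- seq_len(n)
  # reflect-pad so edges keep comparable variance
  pad <- function(x) c(rev(x[seq_len(half)]), x, rev(x[(n - half + 1):n]))
  t(apply(mat, 1L, function(x) {
    stats::filter(pad(x), w, sides = 2)[(half + 1):(half + n)]
  }))
}

check_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
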