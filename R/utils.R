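# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All stochastic operations in the package
# take an explicit seed and go through this, so no global state leaks.
.with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
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
  force(expr)
}

# Separable Gaussian blur with edge renormalization: the kernel is truncated
# at +/- 4 sigma and re-normalized where it overhangs the image border, so no
# intensity is invented or wrapped across edges (ImageJ-like semantics).
# Implemented as two banded-matrix products; exact and size-agnostic.
.blur_op <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  d <- outer(seq_len(n), seq_len(n), "-")
  k <- exp(-(d * d) / (2 * sigma * sigma))
  k[abs(d) > r] <- 0
  k / rowSums(k)
}

.gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  kr <- .blur_op(nrow(mat), sigma)
  kc <- .blur_op(ncol(mat), sigma)
  kr %*% mat %*% t(kc)
}

# Region = c(row_min, row_max, col_min, col_max), 1-based inclusive.
.check_region <- function(region, dim, what = "region") {
  if (!is.numeric(region) || length(region) != 4L) {
    stop(sprintf("`%s` must be c(row_min, row_max, col_min, col_max)", what),
         call. = FALSE)
  }
  region <- as.integer(region)
  if (region[1] < 1L || region[3] < 1L || region[2] > dim[1] ||
      region[4] > dim[2] || region[1] > region[2] || region[3] > region[4]) {
    stop(sprintf("`%s` [%s] lies outside the %d x %d image",
                 what, paste(region, collapse = ", "), dim[1], dim[2]),
         call. = FALSE)
  }
  region
}

.stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  }
  invisible(x)
}
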