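#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards. All stochastic steps in the package
# funnel through this so a pipeline seed fully determines every draw.
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a parent seed and a stream label; keeps every
# stage's randomness independent while reproducible from one master seed.
child_seed <- function(seed, stream) {
  s <- utf8ToInt(as.character(stream))
  h <- sum(s * seq_along(s))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Shift a 3D array by (dx, dy, dz) with edge replication.
shift3d <- function(a, dx, dy, dz) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1]) + dx, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1L), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1L), d[3])
  a[ix, iy, iz, drop = FALSE]
}

# Separable convolution of a 3D array with a 1D kernel along one dimension,
# edge-replicated. Used for Gaussian smoothing of random fields and LoG.
conv1d_dim <- function(a, k, dim) {
  r <- (length(k) - 1L) / 2L
  if (r == 0) return(a * k)
  out <- array(0, dim(a))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    sh <- switch(dim,
      shift3d(a, off, 0L, 0L),
      shift3d(a, 0L, off, 0L),
      shift3d(a, 0L, 0L, off))
    out <- out + k[j] * sh
  }
  out
}

gaussian_smooth3d <- function(a, sigma, sigma_z = sigma) {
  kxy <- gaussian_kernel_1d(sigma)
  kz <- gaussian_kernel_1d(sigma_z)
  a <- conv1d_dim(a, kxy, 1L)
  a <- conv1d_dim(a, kxy, 2L)
  conv1d_dim(a, kz, 3L)
}

# Spatially correlated Gaussian field with unit variance: white noise
# smoothed in-plane with `sigma` voxels, then rescaled to sd 1. Small
# `sigma` approaches white noise (rough, high local entropy); large
# `sigma` gives smooth, low-entropy texture.
correlated_field <- function(dims, sigma, sigma_z = 0.5) {
  f <- array(stats::rnorm(prod(dims)), dims)
  f <- gaussian_smooth3d(f, sigma, sigma_z)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) return(array(0, dims))
  f / s
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
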