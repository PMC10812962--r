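#' Derive a reproducible sub-stream seed from a root seed and a label
#'
#' All randomness in the package flows from one root seed through named
#' sub-streams, so pipeline stages are independently reproducible. The
#' derivation is a 31-ary polynomial hash of the label folded into the
#' root seed, reduced modulo 2^31 - 1 (valid R integer range).
#'
#' @param seed Integer root seed.
#' @param label Character stream label, e.g. `"phantom:S001"`.
#' @return A single integer seed.
#' @export
#' @examples
#' deriveSeed(42L, "phantom:S001")
deriveSeed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- abs(as.double(seed)) %% 2147483647
  for (b in utf8ToInt(label)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

# Evaluate `code` under a temporary RNG state seeded from (seed, label).
withStream <- function(seed, label, code) {
  withr::with_seed(deriveSeed(seed, label), code)
}

#' Smooth standardized Gaussian random field
#'
#' White Gaussian noise smoothed by a separable, truncation-renormalized
#' Gaussian kernel along each array dimension, then standardized to zero
#' mean and unit variance. Used for within-tissue spatial variation of
#' relaxation times and for multiplicative coil-bias fields.
#'
#' @param dims Integer vector of array dimensions (slices, rows, cols).
#' @param scale Smoothness length in voxels (Gaussian sigma) applied to
#'   the in-plane (row, col) dimensions; the slice dimension uses
#'   `max(1, scale / 4)` since slices are much thicker than pixels.
#' @return Numeric array of dimension `dims` with mean 0, sd 1.
#' @export
smoothField <- function(dims, scale = 6) {
  stopifnot(length(dims) == 3L, all(dims >= 1), scale > 0)
  x <- array(stats::rnorm(prod(dims)), dim = dims)
  sig <- c(max(1, scale / 4), scale, scale)
  for (d in 1:3) {
    if (dims[d] > 1) x <- gsmooth1(x, d, sig[d])
  }
  s <- stats::sd(x)
  if (s < .Machine$double.eps) s <- 1
  (x - mean(x)) / s
}

# Gaussian smoothing of array `x` along dimension `d`, sigma in voxels.
# Edge handling: truncated kernel renormalized per row (no wrap-around).
gsmooth1 <- function(x, d, sigma) {
  n <- dim(x)[d]
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok]
  }
  M <- M / rowSums(M)
  perm <- c(d, setdiff(1:3, d))
  xp <- aperm(x, perm)
  dp <- dim(xp)
  dim(xp) <- c(dp[1], prod(dp[-1]))
  xp <- M %*% xp
  dim(xp) <- dp
  aperm(xp, order(perm))
}
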