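## Relaxometry module: voxelwise mono-exponential Levenberg-Marquardt
## fitting of registered echo series, S(t) = S0 * exp(-t / T).

#' Fit mono-exponential relaxation maps from an echo series
#'
#' Per-voxel two-parameter (S0, T) nonlinear least squares under the
#' model `S(t) = S0 * exp(-t / T)`, solved by a vectorized
#' Levenberg-Marquardt iteration (all voxels advanced simultaneously;
#' the 2x2 damped normal equations are solved in closed form per voxel).
#' Initialization is a log-linear least-squares fit of
#' `log(max(S, eps))` against t; the LM iterations themselves see the
#' raw intensities. T is clamped to `bounds`, with the converged flag
#' FALSE at the clamp; all-zero voxel series are marked non-converged
#' with `T = bounds[1]`. No spatial regularization is applied.
#'
#' @param series An [EchoSeries-class] (>= 2 echoes).
#' @param bounds Feasible T range in ms, default c(1, 300); this is the
#'   fit range, distinct from the \[0, 150\] display/clip range.
#' @param initStrategy `"loglinear"` (default) or `"fixed"` (start at the
#'   mid-point of `bounds` with S0 = first echo).
#' @param mask Optional 3D logical array; voxels outside are skipped
#'   (reported non-converged with `T = bounds[1]`, S0 = 0).
#' @param maxIter Maximum LM iterations (default 200).
#' @param relTol Relative convergence tolerance on the parameter step
#'   (default 1e-8).
#' @return A [FitResult-class].
#' @export
fitMonoexponential <- function(series, bounds = c(1, 300),
                               initStrategy = c("loglinear", "fixed"),
                               mask = NULL, maxIter = 200, relTol = 1e-8) {
  stopifnot(is(series, "EchoSeries"))
  initStrategy <- match.arg(initStrategy)
  if (!(bounds[1] > 0 && bounds[1] < bounds[2]))
    stop("bounds must satisfy 0 < lo < hi")
  t <- series@timesMs
  ne <- length(t)
  dims <- dim(series@data)[-1]
  nvox <- prod(dims)
  Y <- matrix(aperm(series@data, c(2, 3, 4, 1)), nvox, ne)

  active <- rep(TRUE, nvox)
  if (!is.null(mask)) active <- as.vector(mask)
  allZero <- rowSums(abs(Y)) == 0
  fitIdx <- which(active & !allZero)

  Tv <- rep(bounds[1], nvox)
  S0v <- numeric(nvox)
  resv <- numeric(nvox)
  conv <- rep(FALSE, nvox)

  if (length(fitIdx)) {
    fit <- lmMonoexp(Y[fitIdx, , drop = FALSE], t, bounds, initStrategy,
                     maxIter, relTol)
    Tv[fitIdx] <- fit$T
    S0v[fitIdx] <- fit$S0
    resv[fitIdx] <- fit$resNorm
    conv[fitIdx] <- fit$converged
  }

  mk <- function(x) { dim(x) <- dims; x }
  map <- QuantMap(mk(Tv), series@kind, series@spacing,
                  fitQuality = mk(resv))
  new("FitResult", map = map, s0Map = mk(S0v),
      convergedMask = mk(conv), residualMap = mk(resv))
}

# Vectorized LM for the mono-exponential model on an nvox x ne matrix.
lmMonoexp <- function(Y, t, bounds, initStrategy, maxIter, relTol) {
  nvox <- nrow(Y); ne <- length(t)
  tlo <- bounds[1]; thi <- bounds[2]

  if (initStrategy == "loglinear") {
    eps <- 1e-6 * max(abs(Y))
    L <- log(pmax(Y, eps))
    tm <- mean(t)
    tc <- t - tm
    stt <- sum(tc^2)
    slope <- as.vector(L %*% tc) / stt
    inter <- rowMeans(L) - slope * tm
    T0 <- ifelse(slope < 0, -1 / slope, thi)
    T0 <- pmin(pmax(T0, tlo), thi)
    S0 <- exp(pmin(inter, log(.Machine$double.xmax) / 2))
  } else {
    T0 <- rep((tlo + thi) / 2, nvox)
    S0 <- pmax(Y[, 1], .Machine$double.eps)
  }
  Tv <- T0

  Emat <- function(Tv) exp(outer(1 / Tv, t, function(iT, tt) -tt * iT))
  cost <- function(S0, Tv, Ym) {
    R <- S0 * Emat(Tv) - Ym
    rowSums(R * R)
  }

  lambda <- rep(1e-3, nvox)
  f <- cost(S0, Tv, Y)
  converged <- rep(FALSE, nvox)
  clamped <- rep(FALSE, nvox)

  for (it in seq_len(maxIter)) {
    open <- which(!converged)
    if (!length(open)) break
    E <- Emat(Tv[open])
    S0o <- S0[open]; To <- Tv[open]
    R <- S0o * E - Y[open, , drop = FALSE]
    # Jacobian columns: d/dS0 = E, d/dT = S0 * t / T^2 * E
    J2 <- (S0o / To^2) * E * rep(t, each = length(open))
    A11 <- rowSums(E * E)
    A12 <- rowSums(E * J2)
    A22 <- rowSums(J2 * J2)
    g1 <- rowSums(E * R)
    g2 <- rowSums(J2 * R)
    lam <- lambda[open]
    M11 <- A11 * (1 + lam); M22 <- A22 * (1 + lam)
    det <- M11 * M22 - A12 * A12
    det[abs(det) < 1e-300] <- 1e-300
    d1 <- (-g1 * M22 + g2 * A12) / det
    d2 <- (-g2 * M11 + g1 * A12) / det
    S0n <- S0o + d1
    Tn <- pmin(pmax(To + d2, tlo), thi)
    fn <- cost(S0n, Tn, Y[open, , drop = FALSE])
    better <- fn <= f[open]
    accI <- open[better]
    S0[accI] <- S0n[better]
    Tv[accI] <- Tn[better]
    f[accI] <- fn[better]
    lambda[accI] <- pmax(lambda[accI] * 0.3, 1e-12)
    rejI <- open[!better]
    lambda[rejI] <- pmin(lambda[rejI] * 3, 1e10)
    step <- pmax(abs(d1) / (abs(S0o) + 1e-12), abs(d2) / (abs(To) + 1e-12))
    converged[open[better & step < relTol]] <- TRUE
  }
  clamped <- Tv <= tlo + 1e-12 | Tv >= thi - 1e-12
  list(S0 = S0, T = Tv, resNorm = sqrt(f),
       converged = converged & !clamped)
}

#' Clip a quantitative map to a display range
#'
#' Values outside `[lo, hi]` are replaced by the nearer bound. The
#' number of clipped voxels is attached as attribute `"clipCount"` on
#' the returned map's values and reported via [message()].
#'
#' @param map A [QuantMap-class].
#' @param lo,hi Clip bounds in ms (default 0 and 150).
#' @param quiet Suppress the message.
#' @return A clipped [QuantMap-class].
#' @export
clipMap <- function(map, lo = 0, hi = 150, quiet = TRUE) {
  stopifnot(is(map, "QuantMap"), lo < hi)
  v <- map@values
  n <- sum(v < lo | v > hi)
  v <- pmin(pmax(v, lo), hi)
  attr(v, "clipCount") <- n
  if (!quiet && n > 0) message(sprintf("clipMap: %d voxels clipped", n))
  QuantMap(v, map@kind, map@spacing, map@fitQuality)
}
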