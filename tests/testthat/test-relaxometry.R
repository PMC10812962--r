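mkSeries <- function(Y, t, kind = "T1rho") {
  # Y: nvox x ne intensity matrix laid out as a (ne, nvox, 1, 1) series
  arr <- array(t(Y), c(length(t), nrow(Y), 1, 1))
  EchoSeries(arr, t, kind)
}

test_that("two noiseless points determine the curve exactly", {
  s <- mkSeries(matrix(c(100, 100 * exp(-1)), 1), c(0, 40))
  fit <- fitMonoexponential(s)
  expect_equal(fit@map@values[1, 1, 1], 40, tolerance = 1e-6 * 40)
  expect_equal(fit@s0Map[1, 1, 1], 100, tolerance = 1e-6 * 100)
  expect_true(fit@convergedMask[1, 1, 1])
})

test_that("noiseless 4-echo series at the TSL schedule recovers T exactly", {
  t <- c(0, 10, 40, 80)
  Ts <- c(25, 40, 55, 70)
  Y <- outer(Ts, t, function(T, tt) 120 * exp(-tt / T))
  fit <- fitMonoexponential(mkSeries(Y, t))
  expect_equal(as.vector(fit@map@values), Ts, tolerance = 1e-6)
  expect_equal(as.vector(fit@s0Map), rep(120, 4), tolerance = 1e-4)
})

test_that("all-zero voxels are flagged non-converged at the lower bound", {
  Y <- rbind(c(0, 0, 0, 0), 90 * exp(-c(0, 10, 40, 80) / 45))
  fit <- fitMonoexponential(mkSeries(Y, c(0, 10, 40, 80)), bounds = c(1, 300))
  expect_false(fit@convergedMask[1, 1, 1])
  expect_equal(fit@map@values[1, 1, 1], 1)
  expect_true(fit@convergedMask[2, 1, 1])
  expect_equal(fit@map@values[2, 1, 1], 45, tolerance = 1e-5)
})

test_that("noisy fits match the exhaustive grid-search oracle within one step", {
  t <- c(0, 10, 40, 80)
  nvox <- 200
  withr::with_seed(77, {
    Ts <- runif(nvox, 30, 60)
    S0s <- runif(nvox, 80, 120)
    Y <- S0s * exp(outer(-1 / Ts, t)) + matrix(rnorm(nvox * 4, 0, 2), nvox)
  })
  fit <- qmapsynth:::lmMonoexp(Y, t, c(1, 300), "loglinear", 200, 1e-8)

  # center each voxel's grid on the (LM-independent) log-linear start
  eps <- 1e-6 * max(abs(Y))
  L <- log(pmax(Y, eps))
  tc <- t - mean(t)
  slope <- as.vector(L %*% tc) / sum(tc^2)
  tInit <- pmin(pmax(-1 / slope, 5), 200)
  s0Init <- exp(rowMeans(L) - slope * mean(t))

  tStep <- 0.01
  s0Step <- 0.01
  for (i in seq_len(25)) {
    tGrid <- seq(tInit[i] - 15, tInit[i] + 15, tStep)
    s0Grid <- seq(s0Init[i] * 0.85, s0Init[i] * 1.15, s0Step)
    E <- exp(outer(-1 / tGrid, t))
    a <- rowSums(E * E)
    b <- as.vector(E %*% Y[i, ])
    costM <- outer(a, s0Grid^2) - 2 * outer(b, s0Grid) + sum(Y[i, ]^2)
    hit <- arrayInd(which.min(costM), dim(costM))
    # the optimum must be interior to the search window
    expect_gt(hit[1], 1); expect_lt(hit[1], length(tGrid))
    expect_gt(hit[2], 1); expect_lt(hit[2], length(s0Grid))
    expect_lt(abs(fit$T[i] - tGrid[hit[1]]), tStep + 1e-9)
    expect_lt(abs(fit$S0[i] - s0Grid[hit[2]]), s0Step + 1e-9)
  }
})

test_that("fits agree with the reference Levenberg-Marquardt implementation", {
  t <- c(0, 10, 40, 80)
  withr::with_seed(3, {
    Ts <- runif(20, 25, 65)
    S0s <- runif(20, 70, 130)
    Y <- S0s * exp(outer(-1 / Ts, t)) + matrix(rnorm(80, 0, 1.5), 20)
  })
  fit <- qmapsynth:::lmMonoexp(Y, t, c(1, 300), "loglinear", 200, 1e-8)
  for (i in 1:20) {
    ref <- minpack.lm::nls.lm(
      par = list(S0 = Y[i, 1], T = 40),
      fn = function(par) par$S0 * exp(-t / par$T) - Y[i, ],
      control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12))
    expect_equal(fit$T[i], ref$par$T, tolerance = 1e-4)
    expect_equal(fit$S0[i], ref$par$S0, tolerance = 1e-4)
  }
})

test_that("scaling all echoes of a voxel changes S0 but not T", {
  t <- c(0, 10, 40, 80)
  y <- 100 * exp(-t / 47)
  Y <- rbind(y, 3.7 * y)
  fit <- fitMonoexponential(mkSeries(Y, t))
  expect_equal(fit@map@values[1, 1, 1], fit@map@values[2, 1, 1],
               tolerance = 1e-9)
  expect_equal(fit@s0Map[2, 1, 1] / fit@s0Map[1, 1, 1], 3.7,
               tolerance = 1e-6)
})

test_that("fit error grows monotonically with the noise level", {
  tr <- tinyTruth()
  acq <- AcquisitionSpec()
  cm <- cartilageMask(tr@labels)
  meds <- vapply(c(0.005, 0.02, 0.08), function(sig) {
    es <- simulateEchoes(tr, acq, "T1rho", noiseSigma = sig, seed = 11)
    f <- fitMonoexponential(es)
    stats::median(abs(f@map@values[cm] - tr@t1rho@values[cm]) /
                    tr@t1rho@values[cm])
  }, 1.0)
  expect_true(all(diff(meds) > 0))
})

test_that("round trip: simulate then fit recovers the phantom truth", {
  tr <- tinyTruth()
  acq <- AcquisitionSpec()
  cm <- cartilageMask(tr@labels)

  es0 <- simulateEchoes(tr, acq, "T2", noiseSigma = 0)
  f0 <- fitMonoexponential(es0)
  expect_lt(max(abs(f0@map@values[cm] - tr@t2@values[cm]) / tr@t2@values[cm]),
            1e-6)

  es1 <- simulateEchoes(tr, acq, "T2", noiseSigma = 0.01, seed = 2)
  f1 <- fitMonoexponential(es1)
  med <- stats::median(abs(f1@map@values[cm] - tr@t2@values[cm]) /
                         tr@t2@values[cm])
  expect_lt(med, 0.02)
})

test_that("clipMap projects onto the display range and counts clips", {
  v <- array(c(-3, 75, 200, 149.9, 0, 150), c(1, 2, 3))
  m <- QuantMap(pmax(v, 0), "T1rho") # construct a valid map first
  m@values <- v # then inject out-of-range values to exercise clipping
  out <- clipMap(m, 0, 150)
  expect_equal(as.vector(out@values), c(0, 75, 150, 149.9, 0, 150))
  expect_equal(attr(out@values, "clipCount"), 2)
  expect_gte(min(out@values), 0)
  expect_lte(max(out@values), 150)
  # in-range map is unchanged
  ok <- QuantMap(array(runif(8, 0, 150), c(2, 2, 2)), "T2")
  expect_equal(clipMap(ok)@values[seq_len(8)], ok@values[seq_len(8)])
})
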