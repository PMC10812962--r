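test_that("nmse matches hand computations and brute force", {
  # hand fixture: truth [3,4], pred [4,4] -> 100 * 1 / 25 = 4%
  tr <- array(c(3, 4), c(1, 1, 2))
  pr <- array(c(4, 4), c(1, 1, 2))
  expect_equal(nmse(pr, tr), 4.0)
  expect_equal(nmse(tr, tr), 0)

  withr::with_seed(1, {
    a <- array(runif(4 * 8 * 8, 0, 150), c(4, 8, 8))
    b <- array(runif(4 * 8 * 8, 0, 150), c(4, 8, 8))
    m <- array(runif(4 * 8 * 8) > 0.4, c(4, 8, 8))
  })
  brute <- 100 * sum((a[m] - b[m])^2) / sum(b[m]^2)
  expect_equal(nmse(a, b, m), brute, tolerance = 1e-9)
  expect_warning(v <- nmse(a, array(0, dim(a))), "all zero")
  expect_true(is.na(v))
})

test_that("psnr follows the log identity and brute force", {
  tr <- array(0, c(1, 2, 2))
  pr <- array(150, c(1, 2, 2)) # MSE = range^2 -> 0 dB
  expect_equal(psnr(pr, tr, dataRange = 150), 0)
  # halving all errors adds 10*log10(4) = 6.0206 dB
  expect_equal(psnr(pr / 2, tr, dataRange = 150) - psnr(pr, tr, dataRange = 150),
               10 * log10(4), tolerance = 1e-9)
  expect_identical(psnr(tr, tr), Inf)
  withr::with_seed(2, {
    a <- array(runif(64, 0, 150), c(4, 4, 4))
    b <- array(runif(64, 0, 150), c(4, 4, 4))
  })
  expect_equal(psnr(a, b), 10 * log10(150^2 / mean((a - b)^2)),
               tolerance = 1e-9)
})

test_that("ssim is 1 for identical volumes and penalizes luminance shifts", {
  withr::with_seed(3, v <- array(runif(2 * 24 * 24, 20, 80), c(2, 24, 24)))
  expect_equal(ssimVolume(v, v), 1.0, tolerance = 1e-12)
  shifted <- v + 50
  expect_lt(ssimVolume(shifted, v), 0.9)
  expect_error(ssimVolume(array(0, c(1, 6, 6)), array(0, c(1, 6, 6))),
               "smaller than")
})

test_that("ssim matches an independent windowed recomputation", {
  withr::with_seed(4, {
    x <- matrix(runif(20 * 20, 0, 150), 20)
    y <- pmin(pmax(x + matrix(rnorm(400, 0, 15), 20), 0), 150)
  })
  mine <- qmapsynth:::ssimSlice(x, y, 150)
  ref <- naiveSsimSlice(x, y, 150)
  expect_equal(mine, ref, tolerance = 1e-6)
})

test_that("ssim matches the scikit-image reference implementation", {
  py <- Sys.which("python")
  withr::with_seed(5, {
    x <- matrix(runif(24 * 24, 0, 150), 24)
    y <- pmin(pmax(x + matrix(rnorm(576, 0, 10), 24), 0), 150)
  })
  d <- withr::local_tempdir()
  write.table(x, file.path(d, "x.csv"), row.names = FALSE, col.names = FALSE)
  write.table(y, file.path(d, "y.csv"), row.names = FALSE, col.names = FALSE)
  code <- paste(
    "import numpy as np",
    "from skimage.metrics import structural_similarity as ssim",
    sprintf("x = np.loadtxt('%s')", file.path(d, "x.csv")),
    sprintf("y = np.loadtxt('%s')", file.path(d, "y.csv")),
    "print('%.12f' % ssim(x, y, data_range=150.0, gaussian_weights=True,",
    "      sigma=1.5, use_sample_covariance=False))",
    sep = "\n")
  ref <- as.numeric(system2(py, c("-c", shQuote(code)), stdout = TRUE))
  expect_equal(qmapsynth:::ssimSlice(x, y, 150), ref, tolerance = 1e-6)
})

test_that("pearson correlation matches closed forms and cor.test", {
  x <- c(1, 3, 5, 9, 11)
  expect_equal(pearsonCorr(x, 2 * x + 1)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearsonCorr(x, -x)$r, -1.0, tolerance = 1e-12)
  withr::with_seed(6, { a <- rnorm(40); b <- a + rnorm(40) })
  pc <- pearsonCorr(a, b)
  # brute-force formula
  rBrute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pc$r, rBrute, tolerance = 1e-12)
  ct <- stats::cor.test(a, b)
  expect_equal(pc$p, ct$p.value, tolerance = 1e-12)
  expect_equal(pc$dof, unname(ct$parameter))
  expect_error(pearsonCorr(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("compartment means aggregate correctly and conserve totals", {
  tr <- tinyTruth()
  v <- array(7.5, dim(tr@labels@labelVolume))
  cm <- compartmentMeans(v, tr@labels)
  expect_true(all(abs(cm - 7.5) < 1e-12))

  # hand-built two-region toy
  lv <- array(0L, c(1, 8, 8))
  lv[1, 1:2, 1] <- 3L # MF
  lv[1, 3, 1] <- 4L   # LF
  labs <- CompartmentLabels(lv)
  vals <- array(0, c(1, 8, 8))
  vals[1, 1:2, 1] <- c(10, 20)
  vals[1, 3, 1] <- 30
  m <- compartmentMeans(vals, labs, c("MF", "LF"))
  expect_equal(unname(m), c(15, 30))

  # conservation: sum over compartments of count * mean = cartilage sum
  allm <- compartmentMeans(tr@t1rho, tr@labels)
  counts <- vapply(cartilageCompartments,
                   function(nm) sum(compartmentMask(tr@labels, nm)), 1L)
  expect_equal(sum(allm * counts),
               sum(tr@t1rho@values[cartilageMask(tr@labels)]),
               tolerance = 1e-9)
  # empty compartments are missing, not 0; unknown names rejected
  expect_true(is.na(compartmentMeans(vals, labs, "PAT")[["PAT"]]))
  expect_error(compartmentMeans(vals, labs, "XX"), "unknown label")
})

test_that("Bland-Altman closed forms hold on hand-computable fixtures", {
  ba0 <- blandAltman(c(10, 20), c(10, 20))
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))

  # pairs (10 -> 12), (20 -> 18): d = (+2, -2)
  ba <- blandAltman(c(10, 20), c(12, 18))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd, sqrt(8), tolerance = 1e-12)
  expect_equal(unname(ba$loa["upper"]), 1.96 * sqrt(8), tolerance = 1e-12)
  expect_equal(ba$table$difference, c(2, -2))

  # translation equivariance: constant added to pred shifts bias only
  withr::with_seed(7, { tm <- runif(12, 30, 50); pm <- tm + rnorm(12) })
  b1 <- blandAltman(tm, pm)
  b2 <- blandAltman(tm, pm + 3)
  expect_equal(b2$bias, b1$bias + 3, tolerance = 1e-12)
  expect_equal(diff(b2$loa), diff(b1$loa), tolerance = 1e-12)
  expect_true(b1$loa["lower"] <= b1$bias && b1$bias <= b1$loa["upper"])
  expect_error(blandAltman(1, 2), "at least 2")
})

test_that("quantification error rate follows the ratio construction", {
  tm <- c(40, 45, 38, 42)
  q0 <- quantificationError(tm, tm)
  expect_equal(q0$errorPct, 0)
  expect_true(q0$clinicallyAcceptable)
  q5 <- quantificationError(tm * 1.05, tm)
  expect_equal(q5$errorPct, 5.0, tolerance = 1e-12)
  expect_true(q5$clinicallyAcceptable)
  q10 <- quantificationError(tm * 1.10, tm)
  expect_equal(q10$errorPct, 10.0, tolerance = 1e-12)
  expect_false(q10$clinicallyAcceptable)
  expect_equal(q10$threshold, 6.42)
})

test_that("cohort evaluation is exact for perfect predictions and re-aggregates", {
  tr1 <- tinyTruth("S001")
  tr2 <- tinyTruth("S002")
  truths <- list(S001 = tr1@t1rho, S002 = tr2@t1rho)
  labels <- list(S001 = tr1@labels, S002 = tr2@labels)
  rep <- evaluateCohort(truths, truths, labels)
  agg <- rep$in_distribution$aggregated
  expect_equal(agg$mean[agg$metric == "nmse_cartilage"], 0)
  expect_equal(agg$mean[agg$metric == "ssim_volume"], 1.0, tolerance = 1e-12)
  expect_equal(rep$in_distribution$agreement$bias, 0)
  expect_equal(rep$in_distribution$agreement$quantError$errorPct, 0)
  # aggregated mean equals mean of the persisted per-subject values
  per <- rep$in_distribution$perSubject
  expect_equal(agg$mean[agg$metric == "nmse_volume"],
               mean(per$nmse_volume))
})
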