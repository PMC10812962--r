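test_that("phantom generation is deterministic and respects geometry", {
  spec <- tinyPhantomSpec()
  a <- generatePhantom(spec, "S001")
  b <- generatePhantom(spec, "S001")
  expect_identical(a@t1rho@values, b@t1rho@values)
  expect_identical(a@t2@values, b@t2@values)
  expect_identical(a@s0, b@s0)

  other <- generatePhantom(spec, "S002")
  expect_false(identical(a@t1rho@values, other@t1rho@values))

  # label conservation: cartilage mask = union of the six compartments
  lab <- a@labels
  cm <- cartilageMask(lab)
  nPer <- vapply(cartilageCompartments,
                 function(nm) sum(compartmentMask(lab, nm)), 1L)
  expect_gt(min(nPer), 0)
  expect_identical(sum(cm), sum(nPer))

  # every voxel has exactly one label drawn from the table
  expect_true(all(lab@labelVolume %in% lab@labelTable))

  # T1rho > T2 in cartilage, both positive in tissue
  expect_true(all(a@t1rho@values[cm] > a@t2@values[cm]))
})

test_that("matrix too small to hold six compartments is rejected", {
  expect_error(makePhantomLabels(c(2, 16, 16)), "too small")
  expect_error(phantomSpec(matrixSize = c(2, 16, 16)), "too small")
})

test_that("lesion-free phantoms stay within the jitter bound of the smooth field", {
  spec <- tinyPhantomSpec(lesionRate = 0, jitterMs = 0.3)
  tr <- generatePhantom(spec, "S001")
  cm <- cartilageMask(tr@labels)
  # rebuild the deterministic coupling from T2: remove T2's own jitter
  # bound, apply slope, and check no voxel exceeds the combined bound
  a <- spec@couplingSlope
  tp <- spec@tissueParams
  bound <- spec@jitterMs * (1 + a) + 1e-9
  for (nm in cartilageCompartments) {
    m <- compartmentMask(tr@labels, nm)
    b <- tp$t1rho[tp$tissue == nm] - a * tp$t2[tp$tissue == nm]
    resid <- tr@t1rho@values[m] - (a * tr@t2@values[m] + b)
    expect_lt(max(abs(resid)), bound)
  }
})

test_that("lesions elevate T1rho beyond what the T2 coupling explains", {
  spec <- tinyPhantomSpec(lesionRate = 5, lesionMagnitude = 0.3, seed = 7)
  tr <- generatePhantom(spec, "S001")
  a <- spec@couplingSlope
  tp <- spec@tissueParams
  excess <- 0
  for (nm in cartilageCompartments) {
    m <- compartmentMask(tr@labels, nm)
    b <- tp$t1rho[tp$tissue == nm] - a * tp$t2[tp$tissue == nm]
    resid <- tr@t1rho@values[m] - (a * tr@t2@values[m] + b)
    excess <- max(excess, max(resid))
  }
  expect_gt(excess, spec@jitterMs * (1 + a))
})

test_that("sampled cartilage T1rho mean matches the configured mean", {
  # across-subject empirical check of the generator's sampling
  # distribution (subject effects and the spatially correlated field
  # average out over subjects)
  spec <- phantomSpec(matrixSize = c(2, 48, 48), nSubjects = 12,
                      lesionRate = 0, seed = 99)
  tp <- spec@tissueParams
  target <- mean(tp$t1rho[tp$tissue %in% cartilageCompartments])
  means <- vapply(sprintf("S%03d", 1:12), function(id) {
    tr <- generatePhantom(spec, id)
    mean(tr@t1rho@values[cartilageMask(tr@labels)])
  }, 1.0)
  se <- stats::sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * se + 0.5)
})

test_that("echo simulation follows the mono-exponential model", {
  tr <- tinyTruth()
  acq <- AcquisitionSpec()
  es <- simulateEchoes(tr, acq, "T1rho", noiseSigma = 0)

  # t = 0 echo equals S0 exactly
  expect_equal(es@data[1, , , ], tr@s0, tolerance = 1e-12)

  # analytic decay: S(40)/S(0) = exp(-1) at a voxel with T = 40
  cm <- cartilageMask(tr@labels)
  v <- which(cm & abs(tr@t1rho@values - 40) < 0.2)[1]
  idx <- arrayInd(v, dim(cm))
  ratio <- es@data[3, idx[1], idx[2], idx[3]] / es@data[1, idx[1], idx[2], idx[3]]
  expect_equal(ratio, exp(-es@timesMs[3] / tr@t1rho@values[v]), tolerance = 1e-12)
  expect_equal(ratio, exp(-1), tolerance = 0.01)

  # noiseless echoes strictly positive and strictly decreasing in time
  tissue <- tr@s0 > 0
  for (e in 2:4) {
    d <- es@data[e - 1, , , ] - es@data[e, , , ]
    expect_true(all(d[tissue] > 0))
    expect_true(all(es@data[e, , , ][tissue] > 0))
  }

  # noisy simulation deterministic under seed
  n1 <- simulateEchoes(tr, acq, "T2", noiseSigma = 0.02, seed = 5)
  n2 <- simulateEchoes(tr, acq, "T2", noiseSigma = 0.02, seed = 5)
  expect_identical(n1@data, n2@data)
  expect_false(identical(n1@data,
                         simulateEchoes(tr, acq, "T2", noiseSigma = 0.02,
                                        seed = 6)@data))
})

test_that("T1rho series uses TSL times and T2 series uses TE times", {
  tr <- tinyTruth()
  acq <- AcquisitionSpec(tslTimes = c(0, 10, 40, 80),
                         teTimes = c(0, 12.9, 25.7, 51.4))
  expect_identical(echoTimes(simulateEchoes(tr, acq, "T1rho", noiseSigma = 0)),
                   c(0, 10, 40, 80))
  expect_identical(echoTimes(simulateEchoes(tr, acq, "T2", noiseSigma = 0)),
                   c(0, 12.9, 25.7, 51.4))
  expect_error(AcquisitionSpec(tslTimes = c(10, 5)), "increasing")
  expect_error(AcquisitionSpec(tslTimes = 0), "2 times")
})

test_that("identity domain shift returns the input unchanged", {
  tr <- tinyTruth()
  es <- simulateEchoes(tr, AcquisitionSpec(), "T1rho")
  sh <- domainShiftSpec(biasFieldAmplitude = 0, snrScale = 1,
                        globalOffsetMs = 0)
  expect_identical(applyDomainShift(es, sh)@data, es@data)
})

test_that("bias field is shared across echoes and cancels in the decay ratio", {
  tr <- tinyTruth()
  es <- simulateEchoes(tr, AcquisitionSpec(), "T1rho", noiseSigma = 0)
  sh <- domainShiftSpec(biasFieldAmplitude = 0.2, snrScale = 1, seed = 3)
  out <- applyDomainShift(es, sh)

  # ratio image shifted/original identical across echoes at every voxel
  tissue <- tr@s0 > 0
  r1 <- (out@data[1, , , ] / es@data[1, , , ])[tissue]
  for (e in 2:4) {
    re <- (out@data[e, , , ] / es@data[e, , , ])[tissue]
    expect_equal(re, r1, tolerance = 1e-12)
  }
  expect_true(all(r1 > 0))

  # mono-exponential fit of the noiseless shifted series still recovers
  # T exactly (the bias cancels within each voxel's decay)
  fit <- fitMonoexponential(out)
  cm <- cartilageMask(tr@labels)
  relErr <- abs(fit@map@values[cm] - tr@t1rho@values[cm]) / tr@t1rho@values[cm]
  expect_lt(max(relErr), 1e-6)

  # determinism
  out2 <- applyDomainShift(es, sh)
  expect_identical(out@data, out2@data)
})

test_that("snr scaling adds the variance needed to reach the target noise", {
  tr <- tinyTruth()
  es <- simulateEchoes(tr, AcquisitionSpec(), "T1rho", noiseSigma = 0.01)
  sh <- domainShiftSpec(biasFieldAmplitude = 0, snrScale = 2, seed = 8)
  out <- applyDomainShift(es, sh)
  expect_equal(out@noiseSigma, 2 * es@noiseSigma)
  bg <- tr@s0 == 0
  sdObs <- stats::sd(out@data[2, , , ][bg])
  expect_equal(sdObs, out@noiseSigma, tolerance = 0.1)
  expect_error(applyDomainShift(es, domainShiftSpec(snrScale = 0.5)),
               "removing noise")
})

test_that("cohorts are reproducible and reject duplicate ids", {
  spec <- tinyPhantomSpec()
  c1 <- makeCohort(spec)
  c2 <- makeCohort(spec)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$truths$S001@t1rho@values, c2$truths$S001@t1rho@values)
  expect_identical(c1$echoes$S002$T2@data, c2$echoes$S002$T2@data)
  expect_equal(nrow(c1$manifest), 2)
  expect_false(anyDuplicated(c1$manifest$subjectId) > 0)
  expect_error(makeCohort(spec, subjectIds = c("A", "A")), "duplicate")
})

test_that("a cohort regenerated from its saved spec file is voxel-identical", {
  dir <- withr::local_tempdir()
  spec <- tinyPhantomSpec()
  c1 <- makeCohort(spec, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  spec2 <- qmapsynth:::phantomSpecFromList(
    yaml::read_yaml(file.path(dir, "phantom_spec.yaml")))
  c2 <- makeCohort(spec2)
  expect_identical(c1$truths$S001@t1rho@values, c2$truths$S001@t1rho@values)
  expect_identical(c1$echoes$S001$T1rho@data, c2$echoes$S001$T1rho@data)
  # written echo stack round-trips through NIfTI within float32
  es <- readEchoes(file.path(dir, "S001_t1rho_echoes.nii"),
                   c1$echoes$S001$T1rho@timesMs, "T1rho")
  expect_equal(es@data, c1$echoes$S001$T1rho@data, tolerance = 1e-6)
})
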