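## Phantom module: stylized sagittal knee phantoms with six cartilage
## compartments, mono-exponential multi-echo simulation and
## coil/scanner domain-shift corruption.

#' Build the stylized compartment label volume
#'
#' The phantom is a stylized sagittal knee: a central disc of bone,
#' surrounded by an annular band of cartilage divided into six angular
#' sectors (the six compartments), an outer annulus of muscle, and
#' background beyond. The geometry is identical across slices, giving
#' spatially contiguous curved 3D bands.
#'
#' @param matrixSize Integer (slices, rows, cols); rows/cols >= 32.
#' @return A [CompartmentLabels-class] object.
#' @export
makePhantomLabels <- function(matrixSize) {
  matrixSize <- as.integer(matrixSize)
  if (length(matrixSize) != 3L || matrixSize[2] < 32 || matrixSize[3] < 32)
    stop("matrix too small to place six cartilage compartments (need rows and cols >= 32)")
  ns <- matrixSize[1]; nr <- matrixSize[2]; nc <- matrixSize[3]
  r0 <- (nr + 1) / 2; c0 <- (nc + 1) / 2
  R0 <- min(nr, nc) / 2
  rr <- matrix(seq_len(nr) - r0, nr, nc)
  cc <- matrix(seq_len(nc) - c0, nr, nc, byrow = TRUE)
  d <- sqrt(rr^2 + cc^2)
  theta <- atan2(rr, cc) # (-pi, pi]
  lt <- defaultLabelTable()
  plane <- matrix(lt[["background"]], nr, nc)
  plane[d <= 0.85 * R0] <- lt[["muscle"]]
  cart <- d > 0.44 * R0 & d <= 0.62 * R0
  sector <- pmin(6L, 1L + as.integer(floor((theta + pi) / (pi / 3))))
  for (i in seq_along(cartilageCompartments)) {
    plane[cart & sector == i] <- lt[[cartilageCompartments[i]]]
  }
  plane[d <= 0.44 * R0] <- lt[["bone"]]
  counts <- table(factor(plane, levels = lt))
  if (any(counts[as.character(lt[cartilageCompartments])] < 8))
    stop("matrix too small to place six cartilage compartments")
  vol <- array(rep(plane, each = ns), dim = c(ns, nr, nc))
  # rep(each = ns) interleaves slices first, matching (slice, row, col) layout
  CompartmentLabels(vol)
}

#' Generate one synthetic phantom subject
#'
#' Draws the ground-truth T2 field (per-compartment mean + per-subject
#' shift + one shared smooth spatial field + bounded uniform jitter),
#' derives T1rho deterministically as `a * T2base + b_c` per compartment
#' (plus its own bounded jitter), plants Poisson-distributed focal
#' lesions that elevate T1rho by `lesionMagnitude` and T2 by
#' `t2LesionFraction * lesionMagnitude` (so T1rho carries information
#' beyond T2), and modulates S0 smoothly. Deterministic for a fixed
#' (spec seed, subject id).
#'
#' @param spec A [PhantomSpec-class].
#' @param subjectId Character subject identifier.
#' @return A [PhantomTruth-class] object.
#' @export
generatePhantom <- function(spec, subjectId) {
  stopifnot(is(spec, "PhantomSpec"), is.character(subjectId))
  validObject(spec)
  labels <- makePhantomLabels(spec@matrixSize)
  lv <- labels@labelVolume
  lt <- labels@labelTable
  tp <- spec@tissueParams
  dims <- dim(lv)

  withStream(spec@seed, paste0("phantom:", subjectId), {
    F1 <- smoothField(dims, spec@fieldScale)
    F2 <- smoothField(dims, spec@fieldScale)
    subjShift <- stats::rnorm(length(cartilageCompartments), 0, spec@subjectSd)
    names(subjShift) <- cartilageCompartments

    t2mean <- array(0, dims)
    s0 <- array(0, dims)
    for (i in seq_len(nrow(tp))) {
      m <- lv == lt[[tp$tissue[i]]]
      shift <- if (tp$tissue[i] %in% cartilageCompartments)
        subjShift[[tp$tissue[i]]] else 0
      t2mean[m] <- tp$t2[i] + shift
      s0[m] <- tp$s0[i]
    }
    t2base <- t2mean + spec@t2FieldSd * F1
    s0 <- pmax(0, s0 * (1 + spec@s0FieldSd * F2))
    dim(s0) <- dims

    # deterministic cartilage coupling T1rho = a * T2base + b_c
    a <- spec@couplingSlope
    t1rho <- array(0, dims)
    for (i in seq_len(nrow(tp))) {
      m <- lv == lt[[tp$tissue[i]]]
      if (tp$tissue[i] %in% cartilageCompartments) {
        b <- tp$t1rho[i] - a * tp$t2[i]
        t1rho[m] <- a * t2base[m] + b
      } else {
        t1rho[m] <- tp$t1rho[i] + 0.5 * F1[m]
      }
    }

    # focal lesions
    nLes <- stats::rpois(1, spec@lesionRate)
    cm <- cartilageMask(labels)
    if (nLes > 0 && any(cm)) {
      idx <- which(cm)
      for (l in seq_len(nLes)) {
        center <- arrayInd(sample(idx, 1), dims)
        w <- lesionProfile(dims, center, spec@lesionRadius)
        w[!cm] <- 0 # lesions live in cartilage
        t1rho <- t1rho * (1 + spec@lesionMagnitude * w)
        t2base <- t2base * (1 + spec@t2LesionFraction * spec@lesionMagnitude * w)
      }
    }

    jit <- spec@jitterMs
    t2 <- t2base + stats::runif(prod(dims), -jit, jit)
    t1rho <- t1rho + stats::runif(prod(dims), -jit, jit)
    t2 <- pmax(t2, 1); t1rho <- pmax(t1rho, 1)
    dim(t2) <- dims; dim(t1rho) <- dims

    new("PhantomTruth",
        t1rho = QuantMap(t1rho, "T1rho"),
        t2 = QuantMap(t2, "T2"),
        s0 = s0, labels = labels, subjectId = subjectId, specUsed = spec)
  })
}

# Gaussian lesion profile centered at `center` (slice, row, col); the
# slice axis is weighted x2 since slices are thicker than pixels.
lesionProfile <- function(dims, center, radius) {
  s <- (seq_len(dims[1]) - center[1]) * 2
  r <- seq_len(dims[2]) - center[2]
  c <- seq_len(dims[3]) - center[3]
  d2 <- outer(outer(s^2, r^2, `+`), c^2, `+`)
  exp(-d2 / (2 * radius^2))
}

#' Simulate a registered multi-echo series from a phantom truth
#'
#' Mono-exponential signal model `S(t) = S0 * exp(-t / T)` with `t` the
#' spin-lock times (kind `"T1rho"`) or T2-preparation times (kind
#' `"T2"`), plus additive Gaussian noise (or Rician, per the phantom
#' spec) with sd `noiseSigma * mean cartilage S0`. Echoes are spatially
#' registered by construction.
#'
#' @param truth A [PhantomTruth-class].
#' @param acq An [AcquisitionSpec-class].
#' @param kind `"T1rho"` or `"T2"`.
#' @param noiseSigma Noise sd as a fraction of mean cartilage S0;
#'   defaults to the phantom spec's value.
#' @param seed Integer seed (combined with kind and subject id).
#' @return An [EchoSeries-class].
#' @export
simulateEchoes <- function(truth, acq, kind = c("T1rho", "T2"),
                           noiseSigma = NULL, seed = truth@specUsed@seed) {
  kind <- match.arg(kind)
  stopifnot(is(truth, "PhantomTruth"), is(acq, "AcquisitionSpec"))
  times <- prepTimes(acq, kind)
  Tmap <- if (kind == "T1rho") truth@t1rho@values else truth@t2@values
  if (is.null(noiseSigma)) noiseSigma <- truth@specUsed@noiseSigma
  dims <- dim(Tmap)
  cm <- cartilageMask(truth@labels)
  sigmaAbs <- noiseSigma * mean(truth@s0[cm])
  ne <- length(times)
  data <- array(0, c(ne, dims))
  for (e in seq_len(ne)) {
    data[e, , , ] <- truth@s0 * exp(-times[e] / Tmap)
  }
  if (sigmaAbs > 0) {
    withStream(seed, paste0("echoes:", kind, ":", truth@subjectId), {
      if (truth@specUsed@noiseModel == "gaussian") {
        data <- data + stats::rnorm(length(data), 0, sigmaAbs)
      } else {
        n1 <- stats::rnorm(length(data), 0, sigmaAbs)
        n2 <- stats::rnorm(length(data), 0, sigmaAbs)
        data <- sqrt((data + n1)^2 + n2^2)
      }
      dim(data) <- c(ne, dims)
    })
  }
  EchoSeries(data, times, kind, spacing = truth@t1rho@spacing,
             noiseSigma = sigmaAbs)
}

#' Apply a coil/scanner domain shift to an echo series
#'
#' Multiplies every echo by one smooth positive bias field (shared
#' across echoes, as a coil sensitivity would be), rescales the noise
#' level by `snrScale` (adding independent Gaussian noise of sd
#' `noiseSigma * sqrt(snrScale^2 - 1)`), and optionally regenerates the
#' decay from truth shifted by `globalOffsetMs`. Deterministic under the
#' shift seed. With amplitude 0, snrScale 1 and offset 0 the input is
#' returned unchanged.
#'
#' @param series An [EchoSeries-class].
#' @param shift A [DomainShiftSpec-class].
#' @param truth Optional [PhantomTruth-class]; required when
#'   `globalOffsetMs != 0`.
#' @return A corrupted [EchoSeries-class].
#' @export
applyDomainShift <- function(series, shift, truth = NULL) {
  stopifnot(is(series, "EchoSeries"), is(shift, "DomainShiftSpec"))
  validObject(shift)
  if (shift@biasFieldAmplitude == 0 && shift@snrScale == 1 &&
      shift@globalOffsetMs == 0) {
    return(series)
  }
  data <- series@data
  dims <- dim(data)[-1]
  ne <- dim(data)[1]
  if (shift@globalOffsetMs != 0) {
    if (is.null(truth))
      stop("globalOffsetMs != 0 requires the phantom truth")
    Tmap <- if (series@kind == "T1rho") truth@t1rho@values else truth@t2@values
    Tshift <- pmax(Tmap + shift@globalOffsetMs, 1)
    for (e in seq_len(ne)) {
      noise <- data[e, , , ] - truth@s0 * exp(-series@timesMs[e] / Tmap)
      data[e, , , ] <- truth@s0 * exp(-series@timesMs[e] / Tshift) + noise
    }
  }
  withStream(shift@seed, "domain-shift", {
    if (shift@biasFieldAmplitude > 0) {
      G <- smoothField(dims, shift@biasFieldScale)
      field <- exp(shift@biasFieldAmplitude * G)
      for (e in seq_len(ne)) data[e, , , ] <- data[e, , , ] * field
    }
    sigma <- series@noiseSigma
    if (shift@snrScale != 1) {
      if (shift@snrScale < 1)
        stop("snrScale < 1 would require removing noise already present")
      extra <- sigma * sqrt(shift@snrScale^2 - 1)
      if (extra > 0) data <- data + stats::rnorm(length(data), 0, extra)
      dim(data) <- c(ne, dims)
      sigma <- sigma * shift@snrScale
    }
    EchoSeries(data, series@timesMs, series@kind, series@spacing,
               noiseSigma = sigma)
  })
}

#' Generate a cohort of phantom subjects with their echo series
#'
#' Generates `spec@nSubjects` subjects (ids `S001`, `S002`, ... unless
#' given) from one seed stream, simulates the T1rho- and T2-weighted
#' echo series for each, and assembles a manifest. When `dir` is given,
#' truth maps, labels and 4D echo stacks are written as NIfTI, the
#' manifest as CSV and the generating spec as YAML, so the cohort can be
#' regenerated or reloaded bit-identically.
#'
#' @param spec A [PhantomSpec-class].
#' @param acq An [AcquisitionSpec-class].
#' @param subjectIds Optional character vector of unique ids.
#' @param dir Optional output directory.
#' @return List with elements `truths` (named list of PhantomTruth),
#'   `echoes` (named list of `list(T1rho=, T2=)` EchoSeries) and
#'   `manifest` (data.frame).
#' @export
makeCohort <- function(spec, acq = AcquisitionSpec(), subjectIds = NULL,
                       dir = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  if (is.null(subjectIds))
    subjectIds <- sprintf("S%03d", seq_len(spec@nSubjects))
  if (anyDuplicated(subjectIds)) stop("duplicate subject ids")
  if (length(subjectIds) != spec@nSubjects)
    stop("need exactly nSubjects subject ids")

  truths <- lapply(subjectIds, function(id) generatePhantom(spec, id))
  names(truths) <- subjectIds
  echoes <- lapply(truths, function(tr) {
    list(T1rho = simulateEchoes(tr, acq, "T1rho"),
         T2 = simulateEchoes(tr, acq, "T2"))
  })
  manifest <- data.frame(
    subjectId = subjectIds,
    seed = vapply(subjectIds, function(id)
      deriveSeed(spec@seed, paste0("phantom:", id)), 1L),
    stratum = "in_distribution",
    stringsAsFactors = FALSE)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in subjectIds) {
      writeMap(file.path(dir, paste0(id, "_t1rho_truth.nii")), truths[[id]]@t1rho)
      writeMap(file.path(dir, paste0(id, "_t2_truth.nii")), truths[[id]]@t2)
      writeLabels(file.path(dir, paste0(id, "_labels.nii")), truths[[id]]@labels)
      writeEchoes(file.path(dir, paste0(id, "_t1rho_echoes.nii")),
                  echoes[[id]]$T1rho)
      writeEchoes(file.path(dir, paste0(id, "_t2_echoes.nii")),
                  echoes[[id]]$T2)
    }
    manifest$t1rhoEchoes <- file.path(dir, paste0(subjectIds, "_t1rho_echoes.nii"))
    manifest$t2Echoes <- file.path(dir, paste0(subjectIds, "_t2_echoes.nii"))
    manifest$labels <- file.path(dir, paste0(subjectIds, "_labels.nii"))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
    yaml::write_yaml(phantomSpecToList(spec), file.path(dir, "phantom_spec.yaml"))
  }
  list(truths = truths, echoes = echoes, manifest = manifest)
}
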