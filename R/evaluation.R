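## Evaluation module: similarity and agreement statistics between
## ground-truth and synthetic maps, whole-volume, cartilage-wide and
## per-compartment.

#' Clinically significant change threshold for cartilage T1rho (%)
#'
#' Changes of about 6.42% in cartilage T1rho are considered clinically
#' significant for osteoarthritis assessment; the quantification-error
#' rate is compared against this constant.
#' @export
clinicalThresholdPct <- 6.42

asVolume <- function(x) if (is(x, "QuantMap")) x@values else x

#' Normalized mean square error over a region (percent)
#'
#' `100 * sum((pred - truth)^2) / sum(truth^2)` over the masked voxels.
#' Returns `NA` (flagged via a warning) when the truth is all zero on
#' the mask.
#'
#' @param pred,truth Numeric volumes or [QuantMap-class] objects.
#' @param mask Optional logical array (default: whole volume).
#' @return NMSE in percent.
#' @export
nmse <- function(pred, truth, mask = NULL) {
  p <- asVolume(pred); y <- asVolume(truth)
  stopifnot(identical(dim(p), dim(y)))
  if (is.null(mask)) mask <- array(TRUE, dim(y))
  if (!any(mask)) stop("mask is empty")
  num <- sum((p[mask] - y[mask])^2)
  den <- sum(y[mask]^2)
  if (den == 0) {
    warning("nmse undefined: truth is all zero on the mask")
    return(NA_real_)
  }
  100 * num / den
}

#' Peak signal-to-noise ratio over a region (dB)
#'
#' `10 * log10(dataRange^2 / MSE)` with MSE over the masked voxels.
#' Identical volumes yield `Inf`, which callers exclude from
#' aggregation.
#'
#' @inheritParams nmse
#' @param dataRange Peak value in ms; fixed default 150 (the clip
#'   ceiling) for cross-subject comparability.
#' @return PSNR in dB.
#' @export
psnr <- function(pred, truth, mask = NULL, dataRange = 150) {
  p <- asVolume(pred); y <- asVolume(truth)
  stopifnot(identical(dim(p), dim(y)))
  if (is.null(mask)) mask <- array(TRUE, dim(y))
  if (!any(mask)) stop("mask is empty")
  mse <- mean((p[mask] - y[mask])^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

#' Structural similarity between two map volumes
#'
#' Standard SSIM (Gaussian window, 11 taps, sigma 1.5, K1 = 0.01,
#' K2 = 0.03) computed per slice on whole slices (no mask), with
#' symmetric boundary padding and the filter-radius border cropped from
#' the SSIM map before averaging; the volume score is the mean over
#' slices.
#'
#' @param pred,truth Volumes or [QuantMap-class] objects, same shape.
#' @param dataRange Dynamic range in ms (default 150, the clip ceiling).
#' @return SSIM score in \[0, 1\] for non-negative inputs.
#' @export
ssimVolume <- function(pred, truth, dataRange = 150) {
  p <- asVolume(pred); y <- asVolume(truth)
  stopifnot(identical(dim(p), dim(y)))
  scores <- vapply(seq_len(dim(p)[1]), function(s)
    ssimSlice(p[s, , ], y[s, , ], dataRange), 1.0)
  mean(scores)
}

# SSIM of two 2D matrices.
ssimSlice <- function(x, y, dataRange, sigma = 1.5, radius = 5,
                      K1 = 0.01, K2 = 0.03) {
  if (any(dim(x) < 2 * radius + 1))
    stop("image smaller than the SSIM window")
  C1 <- (K1 * dataRange)^2
  C2 <- (K2 * dataRange)^2
  f <- function(z) gaussFilter2(z, sigma, radius)
  mx <- f(x); my <- f(y)
  vx <- f(x * x) - mx * mx
  vy <- f(y * y) - my * my
  cxy <- f(x * y) - mx * my
  S <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx * mx + my * my + C1) * (vx + vy + C2))
  crop <- S[(radius + 1):(nrow(S) - radius), (radius + 1):(ncol(S) - radius)]
  mean(crop)
}

# Separable Gaussian filter with symmetric boundary padding.
gaussFilter2 <- function(x, sigma, radius) {
  k <- exp(-((-radius):radius)^2 / (2 * sigma^2))
  k <- k / sum(k)
  sym <- function(n) c(radius:1, 1:n, n:(n - radius + 1))
  n1 <- nrow(x); n2 <- ncol(x)
  xp <- x[sym(n1), sym(n2)]
  M1 <- bandMatrix(n1, k, radius)
  M2 <- bandMatrix(n2, k, radius)
  tmp <- M1 %*% xp
  t(M2 %*% t(tmp))
}

# n x (n + 2r) convolution matrix acting on a symmetric-padded signal.
bandMatrix <- function(n, k, r) {
  M <- matrix(0, n, n + 2 * r)
  for (i in seq_len(n)) M[i, i:(i + 2 * r)] <- k
  M
}

#' Pearson correlation with t-test p-value
#'
#' Correlation between paired samples, degrees of freedom `n - 2` and
#' the two-tailed p-value from the t-transform of r.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @return List with `r`, `dof`, `p`.
#' @export
pearsonCorr <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: zero variance")
  r <- stats::cor(x, y)
  dof <- n - 2
  r2 <- min(r^2, 1 - 1e-15)
  tstat <- r * sqrt(dof / (1 - r2))
  p <- 2 * stats::pt(-abs(tstat), dof)
  list(r = r, dof = dof, p = p)
}

#' Mean map value per cartilage compartment
#'
#' Arithmetic mean over each compartment's labeled voxels; empty
#' compartments are reported as `NA` (missing, not 0).
#'
#' @param map A [QuantMap-class] or 3D volume.
#' @param labels A [CompartmentLabels-class].
#' @param compartments Compartment names (default all six).
#' @return Named numeric vector of means in ms.
#' @export
compartmentMeans <- function(map, labels,
                             compartments = cartilageCompartments) {
  v <- asVolume(map)
  stopifnot(identical(dim(v), dim(labels@labelVolume)))
  bad <- setdiff(compartments, names(labels@labelTable))
  if (length(bad)) stop("unknown label code(s): ", paste(bad, collapse = ", "))
  out <- vapply(compartments, function(nm) {
    m <- labels@labelVolume == labels@labelTable[[nm]]
    if (!any(m)) NA_real_ else mean(v[m])
  }, 1.0)
  out
}

#' Bland-Altman agreement of paired means
#'
#' Differences `d = pred - truth`; bias is `mean(d)`, limits of
#' agreement are `bias +/- 1.96 * sd(d)` with the sample (n-1) standard
#' deviation. A plotting table of (pair mean, difference) is returned.
#'
#' @param truthMeans,predMeans Paired numeric vectors (n >= 2).
#' @return List with `bias`, `loa` (lower, upper), `sd`, `n` and
#'   `table` (data.frame mean/difference).
#' @export
blandAltman <- function(truthMeans, predMeans) {
  stopifnot(length(truthMeans) == length(predMeans))
  ok <- is.finite(truthMeans) & is.finite(predMeans)
  truthMeans <- truthMeans[ok]; predMeans <- predMeans[ok]
  n <- length(truthMeans)
  if (n < 2) stop("Bland-Altman needs at least 2 pairs")
  d <- predMeans - truthMeans
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa = c(lower = bias - 1.96 * s, upper = bias + 1.96 * s),
       sd = s, n = n,
       table = data.frame(mean = (predMeans + truthMeans) / 2,
                          difference = d))
}

#' Compartment-mean quantification-error rate (percent)
#'
#' Mean over subject x compartment units of
#' `100 * |mean_pred - mean_truth| / mean_truth`, flagged against the
#' clinically significant change threshold (6.42% by default). Units
#' with zero truth mean are excluded.
#'
#' @param predMeans,truthMeans Paired numeric vectors of unit means, or
#'   [QuantMap-class] volumes together with `labels`.
#' @param labels Optional [CompartmentLabels-class] when maps are given.
#' @param threshold Clinical threshold in percent.
#' @return List with `errorPct`, `clinicallyAcceptable`, `threshold`,
#'   `n`.
#' @export
quantificationError <- function(predMeans, truthMeans, labels = NULL,
                                threshold = clinicalThresholdPct) {
  if (!is.null(labels)) {
    predMeans <- compartmentMeans(predMeans, labels)
    truthMeans <- compartmentMeans(truthMeans, labels)
  }
  ok <- is.finite(predMeans) & is.finite(truthMeans) & truthMeans != 0
  if (!any(ok)) stop("no usable units for quantification error")
  errs <- 100 * abs(predMeans[ok] - truthMeans[ok]) / truthMeans[ok]
  e <- mean(errs)
  list(errorPct = e, clinicallyAcceptable = e < threshold,
       threshold = threshold, n = sum(ok))
}

#' Per-subject similarity metrics for one prediction
#'
#' Whole-volume and cartilage NMSE/PSNR, cartilage voxelwise Pearson r,
#' whole-volume SSIM, and per-compartment NMSE.
#'
#' @param pred,truth [QuantMap-class] volumes.
#' @param labels [CompartmentLabels-class].
#' @param dataRange PSNR/SSIM dynamic range, ms.
#' @return One-row data.frame.
#' @export
subjectMetrics <- function(pred, truth, labels, dataRange = 150) {
  cm <- cartilageMask(labels)
  p <- asVolume(pred); y <- asVolume(truth)
  corC <- pearsonCorr(p[cm], y[cm])$r
  row <- data.frame(
    nmse_volume = nmse(p, y),
    nmse_cartilage = nmse(p, y, cm),
    psnr_volume = psnr(p, y, dataRange = dataRange),
    psnr_cartilage = psnr(p, y, cm, dataRange = dataRange),
    corr_cartilage = corC,
    ssim_volume = ssimVolume(p, y, dataRange))
  for (nm in cartilageCompartments) {
    m <- compartmentMask(labels, nm)
    row[[paste0("nmse_", nm)]] <- if (any(m)) nmse(p, y, m) else NA_real_
  }
  row
}

#' Evaluate a cohort of predictions against truths
#'
#' Computes per-subject similarity metrics and subject x compartment
#' mean agreement (Bland-Altman bias and limits of agreement, Pearson r
#' of the compartment means, quantification-error rate), aggregated as
#' mean +/- SD per stratum. The full per-subject table is returned for
#' re-aggregation.
#'
#' @param preds,truths Named lists of [QuantMap-class] (same subjects).
#' @param labelsList Named list of [CompartmentLabels-class].
#' @param strata Optional named character vector (by subject id);
#'   default one stratum `"in_distribution"`.
#' @param dataRange Dynamic range in ms.
#' @return Named list per stratum, each with `perSubject` (data.frame),
#'   `aggregated` (data.frame mean/sd per metric), `agreement` (list:
#'   bias, loa, pearson, quantError) and `compartmentTable`.
#' @export
evaluateCohort <- function(preds, truths, labelsList, strata = NULL,
                           dataRange = 150) {
  ids <- names(preds)
  stopifnot(!is.null(ids), identical(sort(ids), sort(names(truths))))
  if (is.null(strata)) strata <- stats::setNames(rep("in_distribution",
                                                     length(ids)), ids)
  out <- list()
  for (st in unique(strata)) {
    sids <- ids[strata[ids] == st]
    if (!length(sids)) { warning("stratum with 0 subjects omitted: ", st); next }
    per <- do.call(rbind, lapply(sids, function(id) {
      cbind(data.frame(subjectId = id),
            subjectMetrics(preds[[id]], truths[[id]], labelsList[[id]],
                           dataRange))
    }))
    num <- per[, setdiff(names(per), "subjectId"), drop = FALSE]
    agg <- data.frame(
      metric = names(num),
      mean = vapply(num, function(x) mean(x[is.finite(x)]), 1.0),
      sd = vapply(num, function(x) stats::sd(x[is.finite(x)]), 1.0),
      row.names = NULL)
    compTab <- do.call(rbind, lapply(sids, function(id) {
      tm <- compartmentMeans(truths[[id]], labelsList[[id]])
      pm <- compartmentMeans(preds[[id]], labelsList[[id]])
      data.frame(subjectId = id, compartment = names(tm),
                 truthMean = as.numeric(tm), predMean = as.numeric(pm),
                 row.names = NULL)
    }))
    ok <- is.finite(compTab$truthMean) & is.finite(compTab$predMean)
    ba <- blandAltman(compTab$truthMean[ok], compTab$predMean[ok])
    pc <- pearsonCorr(compTab$truthMean[ok], compTab$predMean[ok])
    qe <- quantificationError(compTab$predMean[ok], compTab$truthMean[ok])
    out[[st]] <- list(perSubject = per, aggregated = agg,
                      agreement = list(bias = ba$bias, loa = ba$loa,
                                       sd = ba$sd, pearson = pc,
                                       quantError = qe),
                      compartmentTable = compTab)
  }
  out
}
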