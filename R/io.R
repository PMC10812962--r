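## Interface module: NIfTI I/O for maps, labels and echo stacks, plus
## YAML round-trip serialization of the generating configuration.

#' Write / read a quantitative map as NIfTI-1
#'
#' Maps are stored as float NIfTI-1 volumes with identity orientation
#' and the voxel spacing in pixdim. `readMap` rejects files whose
#' dimensionality is not 3.
#'
#' @param path File path (`.nii`).
#' @param map A [QuantMap-class].
#' @return `writeMap` returns the path invisibly; `readMap` returns a
#'   [QuantMap-class].
#' @export
writeMap <- function(path, map) {
  stopifnot(is(map, "QuantMap"))
  v <- map@values
  attributes(v) <- list(dim = dim(v), pixdim = map@spacing)
  img <- RNifti::asNifti(v, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeMap
#' @param kind Map kind for the loaded volume.
#' @export
readMap <- function(path, kind = c("T1rho", "T2")) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop(sprintf("expected a 3D map volume, got %dD: %s", length(d), path))
  QuantMap(array(as.numeric(img), d), kind,
           spacing = RNifti::pixdim(img)[1:3])
}

#' Write / read a compartment label volume as integer NIfTI-1
#' @param path File path.
#' @param labels A [CompartmentLabels-class].
#' @return `readLabels` returns a [CompartmentLabels-class].
#' @export
writeLabels <- function(path, labels) {
  stopifnot(is(labels, "CompartmentLabels"))
  v <- labels@labelVolume
  attributes(v) <- list(dim = dim(v))
  img <- RNifti::asNifti(v, datatype = "int16")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeLabels
#' @param labelTable Code table for the loaded volume.
#' @export
readLabels <- function(path, labelTable = defaultLabelTable()) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) stop("expected a 3D label volume: ", path)
  CompartmentLabels(array(as.integer(img), d), labelTable)
}

#' Write / read a 4D echo stack as NIfTI-1
#'
#' The echo axis is stored as the 4th NIfTI dimension (slice, row, col,
#' echo) and restored to the package's (echo, slice, row, col) layout on
#' read.
#'
#' @param path File path.
#' @param series An [EchoSeries-class].
#' @return `readEchoes` returns an [EchoSeries-class].
#' @export
writeEchoes <- function(path, series) {
  stopifnot(is(series, "EchoSeries"))
  v <- aperm(series@data, c(2, 3, 4, 1))
  attributes(v) <- list(dim = dim(v), pixdim = c(series@spacing, 1))
  img <- RNifti::asNifti(v, datatype = "float")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeEchoes
#' @param timesMs Per-echo preparation times.
#' @param kind `"T1rho"` or `"T2"`.
#' @param noiseSigma Absolute noise sd (a.u.) recorded with the series.
#' @export
readEchoes <- function(path, timesMs, kind = c("T1rho", "T2"),
                       noiseSigma = 0) {
  kind <- match.arg(kind)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L) stop("expected a 4D echo stack: ", path)
  if (d[4] != length(timesMs))
    stop("echo axis length does not match timesMs")
  EchoSeries(aperm(array(as.numeric(img), d), c(4, 1, 2, 3)), timesMs, kind,
             spacing = RNifti::pixdim(img)[1:3], noiseSigma = noiseSigma)
}

## ------------------------------------------------------------------
## Config serialization (lossless YAML round trip)
## ------------------------------------------------------------------

phantomSpecToList <- function(spec) {
  list(matrixSize = as.integer(spec@matrixSize),
       nSubjects = spec@nSubjects,
       tissueParams = as.list(spec@tissueParams),
       lesionRate = spec@lesionRate,
       lesionMagnitude = spec@lesionMagnitude,
       t2LesionFraction = spec@t2LesionFraction,
       noiseSigma = spec@noiseSigma, noiseModel = spec@noiseModel,
       couplingSlope = spec@couplingSlope, t2FieldSd = spec@t2FieldSd,
       fieldScale = spec@fieldScale, jitterMs = spec@jitterMs,
       subjectSd = spec@subjectSd, s0FieldSd = spec@s0FieldSd,
       lesionRadius = spec@lesionRadius, seed = spec@seed)
}

phantomSpecFromList <- function(x) {
  tp <- as.data.frame(x$tissueParams, stringsAsFactors = FALSE)
  phantomSpec(matrixSize = x$matrixSize, nSubjects = x$nSubjects,
              tissueParams = tp, lesionRate = x$lesionRate,
              lesionMagnitude = x$lesionMagnitude,
              t2LesionFraction = x$t2LesionFraction,
              noiseSigma = x$noiseSigma, noiseModel = x$noiseModel,
              couplingSlope = x$couplingSlope, t2FieldSd = x$t2FieldSd,
              fieldScale = x$fieldScale, jitterMs = x$jitterMs,
              subjectSd = x$subjectSd, s0FieldSd = x$s0FieldSd,
              lesionRadius = x$lesionRadius, seed = x$seed)
}

acquisitionSpecToList <- function(acq) {
  list(tslTimes = acq@tslTimes, teTimes = acq@teTimes,
       metadata = acq@metadata)
}

acquisitionSpecFromList <- function(x) {
  AcquisitionSpec(x$tslTimes, x$teTimes, x$metadata)
}

trainConfigToList <- function(cfg) {
  list(splitFractions = as.list(cfg@splitFractions), nFolds = cfg@nFolds,
       learningRate = cfg@learningRate, maxEpochs = cfg@maxEpochs,
       earlyStopPatience = cfg@earlyStopPatience,
       lossWeightCartilage = cfg@lossWeightCartilage,
       lossVariant = cfg@lossVariant, clipRange = cfg@clipRange,
       intensityScale = cfg@intensityScale, batchSize = cfg@batchSize,
       lrDecayFactor = cfg@lrDecayFactor,
       lrDecayPatience = cfg@lrDecayPatience, seed = cfg@seed)
}

trainConfigFromList <- function(x) {
  trainConfig(splitFractions = unlist(x$splitFractions), nFolds = x$nFolds,
              learningRate = x$learningRate, maxEpochs = x$maxEpochs,
              earlyStopPatience = x$earlyStopPatience,
              lossWeightCartilage = x$lossWeightCartilage,
              lossVariant = x$lossVariant, clipRange = x$clipRange,
              intensityScale = x$intensityScale, batchSize = x$batchSize,
              lrDecayFactor = x$lrDecayFactor,
              lrDecayPatience = x$lrDecayPatience, seed = x$seed)
}

#' Assemble / serialize a pipeline run configuration
#'
#' A run configuration nests the phantom spec, acquisition spec,
#' model spec, training configuration and the root seed; it serializes
#' to YAML losslessly, so a run directory always contains the exact
#' configuration that produced it.
#'
#' @param phantom A [PhantomSpec-class].
#' @param acquisition An [AcquisitionSpec-class].
#' @param model A [SynthModelSpec-class].
#' @param train A [TrainConfig-class].
#' @param seed Root seed for the run.
#' @return A `runConfig` list.
#' @export
runConfig <- function(phantom = phantomSpec(), acquisition = AcquisitionSpec(),
                      model = tinyUNetSpec(), train = trainConfig(),
                      seed = 20260105) {
  structure(list(phantom = phantom, acquisition = acquisition,
                 model = model, train = train, seed = as.integer(seed)),
            class = "runConfig")
}

#' @rdname runConfig
#' @param config A `runConfig`.
#' @param path YAML file path.
#' @export
saveRunConfig <- function(config, path) {
  yaml::write_yaml(list(
    phantom = phantomSpecToList(config$phantom),
    acquisition = acquisitionSpecToList(config$acquisition),
    model = list(baseChannels = config$model@baseChannels,
                 depth = config$model@depth,
                 batchNorm = config$model@batchNorm),
    train = trainConfigToList(config$train),
    seed = config$seed), path)
  invisible(path)
}

#' @rdname runConfig
#' @export
loadRunConfig <- function(path) {
  x <- yaml::read_yaml(path)
  runConfig(phantom = phantomSpecFromList(x$phantom),
            acquisition = acquisitionSpecFromList(x$acquisition),
            model = synthModelSpec(x$model$baseChannels, x$model$depth,
                                   x$model$batchNorm),
            train = trainConfigFromList(x$train),
            seed = x$seed)
}

## Short provenance hash of a serialized config (FNV-1a over the YAML).
configHash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  saveRunConfig(config, tmp)
  s <- paste(readLines(tmp), collapse = "\n")
  h <- 2166136261
  for (b in utf8ToInt(s)) h <- ((bitwXor(as.integer(h %% 2^31), b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}
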