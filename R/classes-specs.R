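## ---------------------------------------------------------------------
## AcquisitionSpec
## ---------------------------------------------------------------------

#' AcquisitionSpec: preparation-time schedules
#'
#' Houses the spin-lock time (TSL) schedule for T1rho weighting and the
#' T2-preparation time (TE) schedule for T2 weighting, in ms, plus
#' free-form acquisition metadata (spin-lock frequency, TR, matrix,
#' slice thickness) that is informational only and never enters any
#' computation.
#'
#' The defaults are the 4-point schedules shared by all acquisition
#' settings this pipeline emulates: TSL 0/10/40/80 ms and
#' TE 0/12.9/25.7/51.4 ms.
#'
#' @slot tslTimes Strictly increasing spin-lock times, ms, first >= 0.
#' @slot teTimes Strictly increasing T2-preparation times, ms.
#' @slot metadata Free-form list.
#' @export
setClass("AcquisitionSpec",
  representation(tslTimes = "numeric", teTimes = "numeric",
                 metadata = "list"))

checkTimes <- function(t, what) {
  if (length(t) < 2L) return(sprintf("%s needs >= 2 times", what))
  if (t[1] < 0) return(sprintf("first %s time must be >= 0", what))
  if (any(diff(t) <= 0)) return(sprintf("%s times must be strictly increasing", what))
  NULL
}

setValidity("AcquisitionSpec", function(object) {
  msg <- c(checkTimes(object@tslTimes, "TSL"), checkTimes(object@teTimes, "TE"))
  if (length(msg)) msg[1] else TRUE
})

#' Construct an AcquisitionSpec
#' @param tslTimes Spin-lock times in ms.
#' @param teTimes T2-preparation times in ms.
#' @param metadata Informational list (never used in computation).
#' @return An [AcquisitionSpec-class] object.
#' @export
AcquisitionSpec <- function(tslTimes = c(0, 10, 40, 80),
                            teTimes = c(0, 12.9, 25.7, 51.4),
                            metadata = list(spinLockFreqHz = 500,
                                            trS = 1.2,
                                            fieldStrengthT = 3)) {
  new("AcquisitionSpec", tslTimes = as.numeric(tslTimes),
      teTimes = as.numeric(teTimes), metadata = metadata)
}

#' Preparation times for one weighting kind
#' @param acq An [AcquisitionSpec-class].
#' @param kind `"T1rho"` (spin-lock times) or `"T2"` (TE times).
#' @return Numeric vector of times in ms.
#' @export
prepTimes <- function(acq, kind) {
  stopifnot(is(acq, "AcquisitionSpec"))
  switch(match.arg(kind, c("T1rho", "T2")),
         T1rho = acq@tslTimes, T2 = acq@teTimes)
}

setMethod("show", "AcquisitionSpec", function(object) {
  cat(sprintf("AcquisitionSpec TSL %s ms | TE %s ms\n",
              paste(object@tslTimes, collapse = "/"),
              paste(object@teTimes, collapse = "/")))
})

## ---------------------------------------------------------------------
## PhantomSpec
## ---------------------------------------------------------------------

#' Default per-tissue relaxation parameters
#'
#' Mean T1rho, T2 (ms) and equilibrium signal S0 (a.u.) per tissue
#' class. Cartilage compartment values are free knobs of the generator:
#' compartment-mean T1rho spans the ~30-52 ms range of knee cartilage at
#' 3T, with T1rho > T2 everywhere, and the T1rho-T2 offset deliberately
#' varies across compartments (4-18 ms) so that T1rho carries
#' compartment-specific information that no single global rescaling of
#' T2 can reproduce — the premise that makes synthesis non-trivial.
#' Background has S0 = 0 (noise-only signal).
#'
#' @return data.frame with columns tissue, t1rho, t2, s0.
#' @export
defaultTissueParams <- function() {
  data.frame(
    tissue = c("MF", "LF", "MT", "LT", "PAT", "TRO",
               "bone", "muscle", "background"),
    t1rho  = c(52, 34, 46, 30, 49, 36, 20, 35, 5),
    t2     = c(32, 30, 28, 26, 34, 33, 15, 28, 5),
    s0     = c(1, 1, 1, 1, 1, 1, 0.15, 0.7, 0),
    stringsAsFactors = FALSE)
}

#' PhantomSpec: generator settings for a synthetic knee cohort
#'
#' Describes one cohort of stylized sagittal knee phantoms: matrix size,
#' number of subjects, per-tissue relaxation parameters, within-tissue
#' spatial variation, focal OA-like T1rho lesions and additive noise.
#'
#' @slot matrixSize Integer (slices, rows, cols); rows/cols >= 32 so the
#'   six compartments can be placed.
#' @slot nSubjects Number of subjects.
#' @slot tissueParams data.frame as [defaultTissueParams()].
#' @slot lesionRate Expected focal T1rho elevations per subject (Poisson).
#' @slot lesionMagnitude Fractional T1rho elevation at a lesion center;
#'   T2 is elevated by `t2LesionFraction * lesionMagnitude`.
#' @slot t2LesionFraction Ratio of the T2 to the T1rho lesion elevation
#'   (default 0.5), encoding that T1rho carries information beyond T2.
#' @slot noiseSigma Additive noise sd as a fraction of mean cartilage S0.
#' @slot noiseModel `"gaussian"` (default) or `"rician"`.
#' @slot couplingSlope Slope a of the deterministic cartilage coupling
#'   T1rho = a * T2 + b_c (per-compartment intercept b_c).
#' @slot t2FieldSd Sd (ms) of the smooth within-tissue T2 field.
#' @slot fieldScale Smoothness length (voxels) of the spatial fields.
#' @slot jitterMs Half-width of the bounded uniform per-voxel jitter (ms)
#'   added independently to T1rho and T2.
#' @slot subjectSd Sd (ms) of the per-subject, per-compartment shift of
#'   the T2 mean (propagates to T1rho through the coupling).
#' @slot s0FieldSd Fractional sd of the smooth S0 modulation.
#' @slot lesionRadius Lesion Gaussian radius in voxels.
#' @slot seed Integer root seed for the cohort.
#' @export
setClass("PhantomSpec",
  representation(matrixSize = "integer", nSubjects = "integer",
                 tissueParams = "data.frame", lesionRate = "numeric",
                 lesionMagnitude = "numeric", t2LesionFraction = "numeric",
                 noiseSigma = "numeric", noiseModel = "character",
                 couplingSlope = "numeric", t2FieldSd = "numeric",
                 fieldScale = "numeric", jitterMs = "numeric",
                 subjectSd = "numeric", s0FieldSd = "numeric",
                 lesionRadius = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  ms <- object@matrixSize
  if (length(ms) != 3L || any(ms < 1))
    return("matrixSize must be 3 positive integers (slices, rows, cols)")
  if (ms[2] < 32 || ms[3] < 32)
    return("matrix too small to place six cartilage compartments (need rows and cols >= 32)")
  tp <- object@tissueParams
  need <- c(cartilageCompartments, "bone", "muscle", "background")
  if (!all(need %in% tp$tissue)) return("tissueParams must cover all tissue classes")
  cart <- tp[tp$tissue %in% cartilageCompartments, ]
  if (any(cart$t1rho <= cart$t2))
    return("cartilage T1rho mean must exceed cartilage T2 mean in every compartment")
  if (any(tp$t1rho <= 0) || any(tp$t2 <= 0)) return("relaxation times must be > 0")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  if (!object@noiseModel %in% c("gaussian", "rician"))
    return("noiseModel must be 'gaussian' or 'rician'")
  if (object@lesionRate < 0 || object@lesionMagnitude < 0)
    return("lesionRate and lesionMagnitude must be >= 0")
  if (object@couplingSlope <= 0) return("couplingSlope must be > 0")
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param matrixSize Integer (slices, rows, cols).
#' @param nSubjects Number of subjects in the cohort.
#' @param tissueParams Per-tissue parameter table.
#' @param lesionRate,lesionMagnitude,t2LesionFraction Lesion model knobs.
#' @param noiseSigma Additive noise sd, fraction of mean cartilage S0.
#' @param noiseModel `"gaussian"` or `"rician"`.
#' @param couplingSlope,t2FieldSd,fieldScale,jitterMs,subjectSd,s0FieldSd,lesionRadius
#'   Field/coupling knobs, see [PhantomSpec-class].
#' @param seed Integer root seed.
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(matrixSize = c(8, 64, 64), nSubjects = 30,
                        tissueParams = defaultTissueParams(),
                        lesionRate = 1.5, lesionMagnitude = 0.25,
                        t2LesionFraction = 0.5,
                        noiseSigma = 0.01, noiseModel = "gaussian",
                        couplingSlope = 1.2, t2FieldSd = 1.5,
                        fieldScale = 6, jitterMs = 0.3,
                        subjectSd = 1.5, s0FieldSd = 0.02,
                        lesionRadius = 4, seed = 20260101) {
  new("PhantomSpec", matrixSize = as.integer(matrixSize),
      nSubjects = as.integer(nSubjects), tissueParams = tissueParams,
      lesionRate = lesionRate, lesionMagnitude = lesionMagnitude,
      t2LesionFraction = t2LesionFraction, noiseSigma = noiseSigma,
      noiseModel = noiseModel, couplingSlope = couplingSlope,
      t2FieldSd = t2FieldSd, fieldScale = fieldScale, jitterMs = jitterMs,
      subjectSd = subjectSd, s0FieldSd = s0FieldSd,
      lesionRadius = lesionRadius, seed = as.integer(seed))
}

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %s voxels, %d subjects, noise %.1f%% S0, lesion rate %.2g\n",
    paste(object@matrixSize, collapse = "x"), object@nSubjects,
    100 * object@noiseSigma, object@lesionRate))
})

## ---------------------------------------------------------------------
## DomainShiftSpec
## ---------------------------------------------------------------------

#' DomainShiftSpec: coil/scanner-change corruption of an echo series
#'
#' Emulates acquisition-condition changes: one smooth multiplicative
#' coil-sensitivity bias field shared across echoes, an SNR rescaling
#' (multiplier on the noise sd) and an optional additive shift of the
#' ground-truth relaxation times.
#'
#' @slot biasFieldAmplitude Fractional modulation amplitude (>= 0); the
#'   field is `exp(amplitude * G)` for a standardized smooth field G.
#' @slot biasFieldScale Spatial smoothness length in voxels.
#' @slot snrScale Multiplier on the noise sd (> 0); values > 1 mean lower
#'   SNR (2 = halved SNR).
#' @slot globalOffsetMs Additive ground-truth shift in ms (requires the
#'   phantom truth at application time).
#' @slot seed Integer seed.
#' @export
setClass("DomainShiftSpec",
  representation(biasFieldAmplitude = "numeric", biasFieldScale = "numeric",
                 snrScale = "numeric", globalOffsetMs = "numeric",
                 seed = "integer"))

setValidity("DomainShiftSpec", function(object) {
  if (object@biasFieldAmplitude < 0) return("biasFieldAmplitude must be >= 0")
  if (object@snrScale <= 0) return("snrScale must be > 0")
  if (object@biasFieldScale <= 0) return("biasFieldScale must be > 0")
  TRUE
})

#' Construct a DomainShiftSpec
#' @param biasFieldAmplitude Fractional bias-field amplitude.
#' @param biasFieldScale Field smoothness length, voxels.
#' @param snrScale Noise-sd multiplier (2 = halved SNR).
#' @param globalOffsetMs Additive ground-truth shift, ms.
#' @param seed Integer seed.
#' @return A [DomainShiftSpec-class] object.
#' @export
domainShiftSpec <- function(biasFieldAmplitude = 0.1, biasFieldScale = 12,
                            snrScale = 2, globalOffsetMs = 0,
                            seed = 20260102) {
  new("DomainShiftSpec", biasFieldAmplitude = biasFieldAmplitude,
      biasFieldScale = biasFieldScale, snrScale = snrScale,
      globalOffsetMs = globalOffsetMs, seed = as.integer(seed))
}

## ---------------------------------------------------------------------
## SynthModelSpec and TrainConfig
## ---------------------------------------------------------------------

#' SynthModelSpec: U-Net architecture settings
#'
#' The network has `depth` encoder levels (one 3x3 convolution each,
#' channels doubling per level, each followed by 2x2 max pooling), a
#' bottleneck convolution, `depth` decoder convolutions (2x nearest
#' upsampling + skip concatenation each) and a final linear 3x3 output
#' convolution: `2 * depth + 2` convolutional layers in total (8 at the
#' default depth 3). ReLU activations and batch normalization follow
#' every convolution except the output layer.
#'
#' @slot baseChannels Channels at the first encoder level.
#' @slot depth Number of pooling levels; input rows/cols must be
#'   divisible by `2^depth`.
#' @slot batchNorm Use batch normalization (default TRUE).
#' @export
setClass("SynthModelSpec",
  representation(baseChannels = "integer", depth = "integer",
                 batchNorm = "logical"))

setValidity("SynthModelSpec", function(object) {
  if (object@baseChannels < 1) return("baseChannels must be >= 1")
  if (object@depth < 1) return("depth must be >= 1")
  TRUE
})

#' Construct a SynthModelSpec
#' @param baseChannels First-level channel count.
#' @param depth Encoder levels (pooling steps).
#' @param batchNorm Use batch normalization.
#' @return A [SynthModelSpec-class] object.
#' @export
synthModelSpec <- function(baseChannels = 16, depth = 3, batchNorm = TRUE) {
  new("SynthModelSpec", baseChannels = as.integer(baseChannels),
      depth = as.integer(depth), batchNorm = batchNorm)
}

#' Tiny U-Net preset for desk-scale experiments
#'
#' 8 base channels at depth 3 (8 convolutional layers, < 1e5 parameters).
#' @return A [SynthModelSpec-class] object.
#' @export
tinyUNetSpec <- function() synthModelSpec(baseChannels = 8, depth = 3)

#' Number of convolutional layers implied by a SynthModelSpec
#' @param spec A [SynthModelSpec-class].
#' @return Integer layer count (`2 * depth + 2`).
#' @export
nConvLayers <- function(spec) 2L * spec@depth + 2L

setMethod("show", "SynthModelSpec", function(object) {
  cat(sprintf("SynthModelSpec: depth %d, base %d channels, %d conv layers%s\n",
              object@depth, object@baseChannels, nConvLayers(object),
              if (object@batchNorm) ", batch norm" else ""))
})

#' TrainConfig: training protocol settings
#'
#' Subject-wise 65:15:20 train/validation/test split, 4-fold
#' cross-validation pool, Adam optimization with early stopping on the
#' validation loss, cartilage-weighted loss (weight 1.5), input/output
#' clipping to \[0, 150\] ms and division by `intensityScale` for
#' normalization.
#'
#' @slot splitFractions Named numeric (train, val, test), sums to 1.
#' @slot nFolds Cross-validation folds (default 4).
#' @slot learningRate Adam learning rate.
#' @slot maxEpochs Maximum training epochs.
#' @slot earlyStopPatience Epochs without validation improvement before
#'   stopping (>= 1).
#' @slot lossWeightCartilage Weight of the cartilage L2 term (1.5).
#' @slot lossVariant `"weighted_l2_l1"` (default), `"l2"` or `"l1"`.
#' @slot clipRange Map clip range in ms, default c(0, 150).
#' @slot intensityScale Divisor normalizing clipped maps to ~\[0, 1\].
#' @slot batchSize Mini-batch size (slices).
#' @slot lrDecayFactor Multiplier applied to the learning rate when the
#'   validation loss plateaus (1 disables the schedule).
#' @slot lrDecayPatience Plateau length in epochs before decaying.
#' @slot seed Integer seed for shuffling and initialization.
#' @export
setClass("TrainConfig",
  representation(splitFractions = "numeric", nFolds = "integer",
                 learningRate = "numeric", maxEpochs = "integer",
                 earlyStopPatience = "integer",
                 lossWeightCartilage = "numeric", lossVariant = "character",
                 clipRange = "numeric", intensityScale = "numeric",
                 batchSize = "integer", lrDecayFactor = "numeric",
                 lrDecayPatience = "integer", seed = "integer"))

setValidity("TrainConfig", function(object) {
  f <- object@splitFractions
  if (length(f) != 3L || abs(sum(f) - 1) > 1e-8)
    return("splitFractions must be 3 fractions summing to 1")
  if (any(f <= 0)) return("all split fractions must be > 0")
  if (object@lossWeightCartilage <= 0) return("lossWeightCartilage must be > 0")
  if (object@earlyStopPatience < 1) return("earlyStopPatience must be >= 1")
  if (!object@lossVariant %in% c("weighted_l2_l1", "l2", "l1"))
    return("unknown lossVariant")
  if (length(object@clipRange) != 2L ||
      object@clipRange[1] >= object@clipRange[2])
    return("clipRange must be (lo, hi) with lo < hi")
  if (object@intensityScale <= 0) return("intensityScale must be > 0")
  if (object@lrDecayFactor <= 0 || object@lrDecayFactor > 1)
    return("lrDecayFactor must be in (0, 1]")
  if (object@lrDecayPatience < 1) return("lrDecayPatience must be >= 1")
  TRUE
})

#' Construct a TrainConfig
#' @param splitFractions Train/val/test fractions.
#' @param nFolds CV folds.
#' @param learningRate Adam learning rate.
#' @param maxEpochs Max epochs.
#' @param earlyStopPatience Early-stopping patience in epochs.
#' @param lossWeightCartilage Cartilage L2 weight.
#' @param lossVariant Loss variant.
#' @param clipRange Clip range, ms.
#' @param intensityScale Normalization divisor.
#' @param batchSize Mini-batch size.
#' @param lrDecayFactor,lrDecayPatience Reduce-on-plateau schedule.
#' @param seed Integer seed.
#' @return A [TrainConfig-class] object.
#' @export
trainConfig <- function(splitFractions = c(train = 0.65, val = 0.15, test = 0.20),
                        nFolds = 4, learningRate = 2e-3, maxEpochs = 80,
                        earlyStopPatience = 12, lossWeightCartilage = 1.5,
                        lossVariant = "weighted_l2_l1",
                        clipRange = c(0, 150), intensityScale = 150,
                        batchSize = 8, lrDecayFactor = 0.5,
                        lrDecayPatience = 4, seed = 20260103) {
  new("TrainConfig", splitFractions = splitFractions,
      nFolds = as.integer(nFolds), learningRate = learningRate,
      maxEpochs = as.integer(maxEpochs),
      earlyStopPatience = as.integer(earlyStopPatience),
      lossWeightCartilage = lossWeightCartilage, lossVariant = lossVariant,
      clipRange = as.numeric(clipRange), intensityScale = intensityScale,
      batchSize = as.integer(batchSize), lrDecayFactor = lrDecayFactor,
      lrDecayPatience = as.integer(lrDecayPatience), seed = as.integer(seed))
}

## ---------------------------------------------------------------------
## SlicePair
## ---------------------------------------------------------------------

#' SlicePair: one training sample
#'
#' A T2 input slice, the T1rho target slice, the cartilage mask slice
#' and the provenance (subject id, slice index) that split integrity
#' depends on. Values are in ms (unnormalized).
#'
#' @slot t2Slice,t1rhoSlice 2D numeric matrices, ms.
#' @slot cartilageMaskSlice 2D logical matrix.
#' @slot subjectId Character.
#' @slot sliceIndex Integer.
#' @export
setClass("SlicePair",
  representation(t2Slice = "matrix", t1rhoSlice = "matrix",
                 cartilageMaskSlice = "matrix", subjectId = "character",
                 sliceIndex = "integer"))

setValidity("SlicePair", function(object) {
  d <- dim(object@t2Slice)
  if (!identical(d, dim(object@t1rhoSlice)) ||
      !identical(d, dim(object@cartilageMaskSlice)))
    return("slice shapes must agree")
  if (!nzchar(object@subjectId)) return("subjectId must be present")
  TRUE
})

#' Build the per-slice training pairs of one subject
#' @param t2Map,t1rhoMap [QuantMap-class] input/target volumes.
#' @param labels [CompartmentLabels-class] for the cartilage mask.
#' @param subjectId Subject identifier.
#' @return List of [SlicePair-class], one per slice.
#' @export
makeSlicePairs <- function(t2Map, t1rhoMap, labels, subjectId) {
  stopifnot(identical(dim(t2Map@values), dim(t1rhoMap@values)))
  cm <- cartilageMask(labels)
  lapply(seq_len(dim(t2Map@values)[1]), function(s) {
    new("SlicePair",
        t2Slice = t2Map@values[s, , ],
        t1rhoSlice = t1rhoMap@values[s, , ],
        cartilageMaskSlice = cm[s, , ],
        subjectId = subjectId, sliceIndex = as.integer(s))
  })
}

## ---------------------------------------------------------------------
## UNetModel
## ---------------------------------------------------------------------

#' UNetModel: a (possibly trained) synthesis network
#'
#' Holds the architecture spec, trainable parameters, batch-norm running
#' statistics and the training configuration used (for identical
#' preprocessing at inference).
#'
#' @slot spec [SynthModelSpec-class].
#' @slot params Named list of parameter arrays.
#' @slot stats Batch-norm running statistics.
#' @slot trained Logical.
#' @slot config The [TrainConfig-class] used for training, or NULL.
#' @export
setClass("UNetModel",
  representation(spec = "SynthModelSpec", params = "list", stats = "list",
                 trained = "logical", config = "ANY"),
  prototype(trained = FALSE, config = NULL))

setMethod("show", "UNetModel", function(object) {
  cat(sprintf("UNetModel: %s, %d parameters, %s\n",
              sprintf("depth %d base %d", object@spec@depth,
                      object@spec@baseChannels),
              parameterCount(object),
              if (object@trained) "trained" else "untrained"))
})

#' Total trainable parameter count of a model
#' @param model A [UNetModel-class].
#' @return Integer.
#' @export
parameterCount <- function(model) {
  length(unlist(model@params, recursive = TRUE, use.names = FALSE))
}

# Apply f to every leaf array of a nested parameter list.
rapplyParams <- function(p, f) {
  if (is.list(p)) lapply(p, rapplyParams, f = f) else f(p)
}
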