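#' Names of the six cartilage compartments
#'
#' Medial/lateral femoral condyle (MF/LF), medial/lateral tibial (MT/LT),
#' patellar (PAT) and trochlear (TRO) cartilage.
#' @export
cartilageCompartments <- c("MF", "LF", "MT", "LT", "PAT", "TRO")

#' Default tissue label table
#'
#' Integer codes for the phantom's tissue classes: background, bone,
#' muscle and the six cartilage compartments. Codes are distinct, so the
#' six cartilage regions are disjoint by construction.
#' @return Named integer vector.
#' @export
defaultLabelTable <- function() {
  c(background = 0L, bone = 1L, muscle = 2L,
    MF = 3L, LF = 4L, MT = 5L, LT = 6L, PAT = 7L, TRO = 8L)
}

## ---------------------------------------------------------------------
## QuantMap: one relaxation-time map in ms
## ---------------------------------------------------------------------

#' QuantMap: a single quantitative relaxation-time map
#'
#' A 3D volume of relaxation times in milliseconds, tagged with its kind
#' (`"T1rho"` or `"T2"`), the voxel spacing (mm, slice/row/col order) and
#' optionally a per-voxel fit-quality (residual norm) volume.
#'
#' @slot values 3D numeric array (slice, row, col), ms, non-negative.
#' @slot kind `"T1rho"` or `"T2"`.
#' @slot spacing Numeric length-3 voxel spacing in mm.
#' @slot fitQuality Optional 3D array of per-voxel residual norms, or NULL.
#' @export
setClass("QuantMap",
  representation(values = "array", kind = "character",
                 spacing = "numeric", fitQuality = "ANY"),
  prototype(fitQuality = NULL))

setValidity("QuantMap", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array (slice, row, col)")
  if (!object@kind %in% c("T1rho", "T2")) return("kind must be 'T1rho' or 'T2'")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (any(!is.finite(v))) return("values must be finite")
  if (min(v) < 0) return("relaxation times must be non-negative")
  fq <- object@fitQuality
  if (!is.null(fq) && !identical(dim(fq), dim(v)))
    return("fitQuality must be NULL or share the values geometry")
  TRUE
})

#' Construct a QuantMap
#' @param values 3D numeric array of relaxation times (ms).
#' @param kind `"T1rho"` or `"T2"`.
#' @param spacing Voxel spacing in mm (slice, row, col).
#' @param fitQuality Optional per-voxel residual norm array.
#' @return A [QuantMap-class] object.
#' @export
QuantMap <- function(values, kind, spacing = c(4, 0.55, 0.55),
                     fitQuality = NULL) {
  new("QuantMap", values = values, kind = kind,
      spacing = as.numeric(spacing), fitQuality = fitQuality)
}

#' @rdname accessors
#' @export
setMethod("mapValues", "QuantMap", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("mapKind", "QuantMap", function(x, ...) x@kind)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "QuantMap", function(x, ...) x@spacing)

#' @export
setMethod("dim", "QuantMap", function(x) dim(x@values))

setMethod("show", "QuantMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("QuantMap <%s> %d x %d x %d voxels, range [%.2f, %.2f] ms\n",
              object@kind, d[1], d[2], d[3],
              min(object@values), max(object@values)))
})

## ---------------------------------------------------------------------
## CompartmentLabels
## ---------------------------------------------------------------------

#' CompartmentLabels: tissue label volume
#'
#' Integer label volume over the phantom geometry plus the code table
#' mapping tissue names to integers. Every voxel carries exactly one
#' label; the cartilage mask is the union of the six compartment codes.
#'
#' @slot labelVolume 3D integer array (slice, row, col).
#' @slot labelTable Named integer vector (see [defaultLabelTable()]).
#' @export
setClass("CompartmentLabels",
  representation(labelVolume = "array", labelTable = "integer"))

setValidity("CompartmentLabels", function(object) {
  lv <- object@labelVolume
  lt <- object@labelTable
  if (length(dim(lv)) != 3L) return("labelVolume must be 3D")
  if (anyDuplicated(lt)) return("label codes must be distinct")
  if (!all(cartilageCompartments %in% names(lt)))
    return("labelTable must contain all six cartilage compartments")
  if (!all(unique(as.integer(lv)) %in% lt))
    return("labelVolume contains codes absent from labelTable")
  TRUE
})

#' Construct CompartmentLabels
#' @param labelVolume 3D integer array.
#' @param labelTable Named integer code table.
#' @return A [CompartmentLabels-class] object.
#' @export
CompartmentLabels <- function(labelVolume, labelTable = defaultLabelTable()) {
  storage.mode(labelVolume) <- "integer"
  new("CompartmentLabels", labelVolume = labelVolume,
      labelTable = labelTable)
}

#' @rdname accessors
#' @export
setMethod("labelTable", "CompartmentLabels", function(x, ...) x@labelTable)

#' @rdname accessors
#' @export
setMethod("cartilageMask", "CompartmentLabels", function(x, ...) {
  codes <- x@labelTable[cartilageCompartments]
  array(x@labelVolume %in% codes, dim = dim(x@labelVolume))
})

#' @rdname accessors
#' @export
setMethod("compartmentMask", "CompartmentLabels", function(x, name, ...) {
  if (!name %in% names(x@labelTable))
    stop("unknown label: ", name)
  array(x@labelVolume == x@labelTable[[name]], dim = dim(x@labelVolume))
})

#' @export
setMethod("dim", "CompartmentLabels", function(x) dim(x@labelVolume))

setMethod("show", "CompartmentLabels", function(object) {
  d <- dim(object@labelVolume)
  n <- sum(cartilageMask(object))
  cat(sprintf("CompartmentLabels %d x %d x %d voxels, %d cartilage voxels\n",
              d[1], d[2], d[3], n))
})

## ---------------------------------------------------------------------
## EchoSeries
## ---------------------------------------------------------------------

#' EchoSeries: a multi-echo weighted image stack
#'
#' 4D intensity volume (echo, slice, row, col) with its preparation-time
#' axis in ms: spin-lock times (TSL) for T1rho weighting, T2-preparation
#' times (TE) for T2 weighting. Echoes are spatially registered by
#' construction. `noiseSigma` records the absolute additive noise sd
#' (a.u.) used at simulation time so that SNR rescaling is well defined.
#'
#' @slot data 4D numeric array (echo, slice, row, col), a.u.
#' @slot timesMs Strictly increasing per-echo preparation times, ms.
#' @slot kind `"T1rho"` or `"T2"`.
#' @slot spacing Voxel spacing in mm.
#' @slot noiseSigma Absolute sd of the additive noise (a.u.); 0 if noiseless.
#' @export
setClass("EchoSeries",
  representation(data = "array", timesMs = "numeric", kind = "character",
                 spacing = "numeric", noiseSigma = "numeric"))

setValidity("EchoSeries", function(object) {
  d <- dim(object@data)
  t <- object@timesMs
  if (length(d) != 4L) return("data must be 4D (echo, slice, row, col)")
  if (length(t) != d[1]) return("length(timesMs) must equal the echo axis")
  if (length(t) < 2L) return("at least 2 echoes are required")
  if (any(diff(t) <= 0)) return("timesMs must be strictly increasing")
  if (t[1] < 0) return("first preparation time must be >= 0")
  if (!object@kind %in% c("T1rho", "T2")) return("kind must be 'T1rho' or 'T2'")
  if (object@noiseSigma < 0) return("noiseSigma must be >= 0")
  TRUE
})

#' Construct an EchoSeries
#' @param data 4D numeric array (echo, slice, row, col).
#' @param timesMs Per-echo preparation times in ms.
#' @param kind `"T1rho"` or `"T2"`.
#' @param spacing Voxel spacing in mm.
#' @param noiseSigma Absolute additive noise sd (a.u.).
#' @return An [EchoSeries-class] object.
#' @export
EchoSeries <- function(data, timesMs, kind, spacing = c(4, 0.55, 0.55),
                       noiseSigma = 0) {
  new("EchoSeries", data = data, timesMs = as.numeric(timesMs), kind = kind,
      spacing = as.numeric(spacing), noiseSigma = noiseSigma)
}

#' @rdname accessors
#' @export
setMethod("echoTimes", "EchoSeries", function(x, ...) x@timesMs)

#' @rdname accessors
#' @export
setMethod("mapKind", "EchoSeries", function(x, ...) x@kind)

#' @export
setMethod("dim", "EchoSeries", function(x) dim(x@data))

setMethod("show", "EchoSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("EchoSeries <%s> %d echoes at t = %s ms, %d x %d x %d voxels\n",
              object@kind, d[1], paste(object@timesMs, collapse = "/"),
              d[2], d[3], d[4]))
})

## ---------------------------------------------------------------------
## PhantomTruth and FitResult
## ---------------------------------------------------------------------

#' PhantomTruth: ground truth for one synthetic subject
#'
#' Ground-truth T1rho and T2 maps, the equilibrium-signal volume S0, the
#' compartment labels and the generating spec for one phantom subject.
#'
#' @slot t1rho,t2 [QuantMap-class] ground-truth maps.
#' @slot s0 3D array, equilibrium signal (a.u.).
#' @slot labels [CompartmentLabels-class].
#' @slot subjectId Character subject identifier.
#' @slot specUsed The generating `PhantomSpec`.
#' @export
setClass("PhantomTruth",
  representation(t1rho = "QuantMap", t2 = "QuantMap", s0 = "array",
                 labels = "CompartmentLabels", subjectId = "character",
                 specUsed = "ANY"))

setValidity("PhantomTruth", function(object) {
  d <- dim(object@t1rho@values)
  if (!identical(d, dim(object@t2@values)) ||
      !identical(d, dim(object@s0)) ||
      !identical(d, dim(object@labels@labelVolume)))
    return("all volumes must share one geometry")
  bg <- object@labels@labelTable[["background"]]
  tissue <- object@labels@labelVolume != bg
  if (any(object@t1rho@values[tissue] <= 0))
    return("t1rho must be > 0 wherever labels != background")
  TRUE
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@t1rho@values)
  cat(sprintf("PhantomTruth '%s' %d x %d x %d voxels\n",
              object@subjectId, d[1], d[2], d[3]))
})

#' FitResult: output of voxelwise mono-exponential fitting
#'
#' Fitted relaxation map plus the companion S0 map, a converged-voxel
#' mask (voxels clamped at the fit bounds or stopped without meeting the
#' tolerance are flagged FALSE, never silently filled) and the per-voxel
#' residual norm.
#'
#' @slot map [QuantMap-class] fitted relaxation times.
#' @slot s0Map 3D array of fitted S0 (a.u.).
#' @slot convergedMask 3D logical array.
#' @slot residualMap 3D array, residual 2-norm per voxel.
#' @export
setClass("FitResult",
  representation(map = "QuantMap", s0Map = "array",
                 convergedMask = "array", residualMap = "array"))

setValidity("FitResult", function(object) {
  d <- dim(object@map@values)
  if (!identical(d, dim(object@s0Map)) ||
      !identical(d, dim(object@convergedMask)) ||
      !identical(d, dim(object@residualMap)))
    return("all volumes must share one geometry")
  if (!is.logical(object@convergedMask)) return("convergedMask must be logical")
  TRUE
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult <%s>: %.1f%% voxels converged\n",
              object@map@kind, 100 * mean(object@convergedMask)))
})
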