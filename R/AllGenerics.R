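#' @import methods
NULL

#' Accessor generics
#'
#' Small accessor generics for the package's S4 containers: map values in
#' ms, map kind (`"T1rho"` or `"T2"`), voxel spacing, echo preparation
#' times, the compartment label table, and the binary cartilage mask.
#'
#' @param x An object.
#' @param ... Passed to methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("mapValues", function(x, ...) standardGeneric("mapValues"))

#' @rdname accessors
#' @export
setGeneric("mapKind", function(x, ...) standardGeneric("mapKind"))

#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x, ...) standardGeneric("voxelSpacing"))

#' @rdname accessors
#' @export
setGeneric("echoTimes", function(x, ...) standardGeneric("echoTimes"))

#' @rdname accessors
#' @export
setGeneric("labelTable", function(x, ...) standardGeneric("labelTable"))

#' @rdname accessors
#' @export
setGeneric("cartilageMask", function(x, ...) standardGeneric("cartilageMask"))

#' @rdname accessors
#' @export
setGeneric("compartmentMask", function(x, name, ...)
  standardGeneric("compartmentMask"))
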