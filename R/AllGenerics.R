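#' Accessors for volume-like objects
#'
#' \code{voxelGrid} returns the geometry; \code{gridDims}, \code{gridSpacing}
#' and \code{gridOrigin} its components; \code{intensities}, \code{labelArray}
#' and \code{probKT} the payload arrays.
#'
#' @param x a \linkS4class{VoxelGrid}, \linkS4class{IntensityVolume},
#'   \linkS4class{LabelMap} or \linkS4class{ProbabilityMap}.
#' @return The requested slot content (see details above).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelGrid", function(x) standardGeneric("voxelGrid"))
#' @rdname accessors
#' @export
setGeneric("gridDims", function(x) standardGeneric("gridDims"))
#' @rdname accessors
#' @export
setGeneric("gridSpacing", function(x) standardGeneric("gridSpacing"))
#' @rdname accessors
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))
#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setGeneric("labelArray", function(x) standardGeneric("labelArray"))
#' @rdname accessors
#' @export
setGeneric("probKT", function(x) standardGeneric("probKT"))

#' @rdname accessors
setMethod("voxelGrid", "Volume3D", function(x) x@grid)
#' @rdname accessors
setMethod("gridDims", "VoxelGrid", function(x) x@dims)
#' @rdname accessors
setMethod("gridDims", "Volume3D", function(x) x@grid@dims)
#' @rdname accessors
setMethod("gridSpacing", "VoxelGrid", function(x) x@spacing)
#' @rdname accessors
setMethod("gridSpacing", "Volume3D", function(x) x@grid@spacing)
#' @rdname accessors
setMethod("gridOrigin", "VoxelGrid", function(x) x@origin)
#' @rdname accessors
setMethod("gridOrigin", "Volume3D", function(x) x@grid@origin)
#' @rdname accessors
setMethod("intensities", "IntensityVolume", function(x) x@values)
#' @rdname accessors
setMethod("labelArray", "LabelMap", function(x) x@labels)
#' @rdname accessors
setMethod("probKT", "ProbabilityMap", function(x) x@p)

#' Apply a transform chain to a volume or label map
#'
#' @param input an \linkS4class{IntensityVolume} or \linkS4class{LabelMap}.
#' @param chain a \linkS4class{TransformChain} (or bare
#'   \linkS4class{AffineTransform}, promoted to a chain).
#' @param fixedGrid the target (fixed-space) \linkS4class{VoxelGrid}.
#' @param mode interpolation: "linear" (intensities) or "nearest" (labels
#'   require nearest -- labels are never interpolated).
#' @return Resampled object of the same class as \code{input}, on
#'   \code{fixedGrid}.
#' @export
setGeneric("applyTransform",
  function(input, chain, fixedGrid, mode = c("linear", "nearest"))
    standardGeneric("applyTransform"))
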