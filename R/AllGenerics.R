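#' @rdname LabelMap-class
#' @param object,x a \code{LabelMap}, \code{EnsembleSet} or
#'   \code{StructureScheme}.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname LabelMap-class
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname LabelMap-class
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))

#' @rdname StructureScheme-class
#' @export
setGeneric("labelIds", function(x) standardGeneric("labelIds"))

#' @rdname StructureScheme-class
#' @export
setGeneric("labelNames", function(x) standardGeneric("labelNames"))

#' @rdname StructureScheme-class
#' @export
setGeneric("structureClasses", function(x) standardGeneric("structureClasses"))

#' @rdname EnsembleSet-class
#' @export
setGeneric("finalPrediction", function(x) standardGeneric("finalPrediction"))

#' @rdname EnsembleSet-class
#' @export
setGeneric("auxiliaries", function(x) standardGeneric("auxiliaries"))

#' @rdname EnsembleSet-class
#' @export
setGeneric("nAux", function(x) standardGeneric("nAux"))

#' Binary mask of one label
#'
#' Returns the boolean occupancy array of a single label id: \code{TRUE}
#' exactly where the voxel value equals \code{labelId}. The masks of all
#' scheme labels plus background partition the grid, since labels are
#' mutually exclusive.
#'
#' @param x a [LabelMap-class].
#' @param labelId an id present in the scheme (or the background id).
#' @return A 3D logical array of the same shape as the volume.
#' @export
setGeneric("binaryMask", function(x, labelId) standardGeneric("binaryMask"))
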