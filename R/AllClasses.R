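#' @import methods
NULL

#' StructureScheme: the label dictionary of a multi-label segmentation
#'
#' A \code{StructureScheme} maps positive integer label ids to anatomical
#' structure names and to a structure class (\code{"bone"} or \code{"muscle"}).
#' The class drives the goodness rule: bones and muscles carry different
#' correction-Dice thresholds. Label id 0 is always background and is not an
#' entry of the scheme.
#'
#' @slot labelIds integer vector of unique positive label ids.
#' @slot labelNames character vector of structure names, parallel to
#'   \code{labelIds}.
#' @slot structureClasses character vector, each \code{"bone"} or
#'   \code{"muscle"}, parallel to \code{labelIds}.
#' @slot backgroundId integer scalar, the background voxel value (0).
#'
#' @seealso [shoulderScheme()] for the default six-structure shoulder scheme,
#'   [readScheme()] to load a scheme from YAML/JSON.
#' @export
setClass("StructureScheme",
  representation(
    labelIds = "integer",
    labelNames = "character",
    structureClasses = "character",
    backgroundId = "integer"
  ),
  prototype(backgroundId = 0L)
)

setValidity("StructureScheme", function(object) {
  msg <- character(0)
  n <- length(object@labelIds)
  if (n == 0L) msg <- c(msg, "scheme must contain at least one label")
  if (length(object@labelNames) != n || length(object@structureClasses) != n)
    msg <- c(msg, "labelIds, labelNames and structureClasses must have equal length")
  if (anyDuplicated(object@labelIds))
    msg <- c(msg, "label ids must be unique")
  if (any(object@labelIds <= object@backgroundId))
    msg <- c(msg, "label ids must exceed the background id")
  bad <- setdiff(unique(object@structureClasses), c("bone", "muscle"))
  if (length(bad))
    msg <- c(msg, sprintf("unknown structure class: %s", paste(bad, collapse = ", ")))
  if (length(object@backgroundId) != 1L)
    msg <- c(msg, "backgroundId must be a single integer")
  if (length(msg)) msg else TRUE
})

#' Construct a StructureScheme
#'
#' @param labelIds integer vector of unique positive label ids.
#' @param labelNames character vector of structure names.
#' @param structureClasses character vector of \code{"bone"}/\code{"muscle"}.
#' @param backgroundId background voxel value, default 0.
#' @return A [StructureScheme-class] object.
#' @examples
#' StructureScheme(1:2, c("humerus", "scapula"), c("bone", "bone"))
#' @export
StructureScheme <- function(labelIds, labelNames, structureClasses,
                            backgroundId = 0L) {
  new("StructureScheme",
    labelIds = as.integer(labelIds),
    labelNames = as.character(labelNames),
    structureClasses = as.character(structureClasses),
    backgroundId = as.integer(backgroundId)
  )
}

#' The default shoulder structure scheme
#'
#' Six structures of the glenohumeral joint and rotator cuff: humerus and
#' scapula (bone), and the four rotator cuff muscles supraspinatus (SSP),
#' subscapularis (SSC), infraspinatus (ISP) and teres minor (TM). The numeric
#' convention is 1 = humerus, 2 = scapula, 3 = SSP, 4 = SSC, 5 = ISP, 6 = TM,
#' 0 = background; it can be overridden by supplying any other
#' [StructureScheme-class].
#'
#' @return A [StructureScheme-class] with six entries.
#' @examples
#' shoulderScheme()
#' @export
shoulderScheme <- function() {
  StructureScheme(
    labelIds = 1:6,
    labelNames = c("humerus", "scapula", "supraspinatus", "subscapularis",
                   "infraspinatus", "teres_minor"),
    structureClasses = c("bone", "bone", "muscle", "muscle", "muscle", "muscle")
  )
}

#' LabelMap: a multi-label 3D segmentation volume
#'
#' A 3D array of non-negative integer voxel values on a regular grid with
#' physical voxel spacing, together with the [StructureScheme-class] that
#' interprets the values. Every non-background voxel value must be an id of
#' the scheme; unknown values are rejected at construction/load time.
#'
#' @slot voxels 3D integer array of label values.
#' @slot spacing numeric length-3 vector of voxel edge lengths in mm,
#'   strictly positive.
#' @slot scheme the [StructureScheme-class].
#'
#' @seealso [readLabelMap()], [writeLabelMap()], [binaryMask()].
#' @export
setClass("LabelMap",
  representation(
    voxels = "array",
    spacing = "numeric",
    scheme = "StructureScheme"
  )
)

setValidity("LabelMap", function(object) {
  msg <- character(0)
  v <- object@voxels
  if (length(dim(v)) != 3L)
    msg <- c(msg, "voxels must be a 3D array")
  if (!is.integer(v))
    msg <- c(msg, "voxels must be stored as integers")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be three strictly positive lengths")
  vals <- unique(as.vector(v))
  fg <- vals[vals != object@scheme@backgroundId]
  unknown <- setdiff(fg, object@scheme@labelIds)
  if (length(unknown))
    msg <- c(msg, sprintf("voxel values not in scheme: %s",
                          paste(sort(unknown), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a LabelMap
#'
#' @param voxels 3D array of non-negative integers (coerced to integer;
#'   non-integral values are an error).
#' @param spacing numeric length-3 voxel spacing in mm.
#' @param scheme a [StructureScheme-class].
#' @return A [LabelMap-class] object.
#' @examples
#' v <- array(0L, c(4, 4, 4)); v[2, 2, 2] <- 1L
#' LabelMap(v, c(1, 1, 1), shoulderScheme())
#' @export
LabelMap <- function(voxels, spacing = c(1, 1, 1), scheme = shoulderScheme()) {
  if (!is.integer(voxels)) {
    if (any(voxels != round(voxels), na.rm = TRUE))
      stop("voxel values must be integers")
    storage.mode(voxels) <- "integer"
  }
  if (anyNA(voxels)) stop("voxel values must not be missing")
  new("LabelMap", voxels = voxels, spacing = as.numeric(spacing),
      scheme = scheme)
}

#' EnsembleSet: a final prediction with its auxiliary predictions
#'
#' Bundles the final (ensemble) segmentation of one case with N >= 2 auxiliary
#' predictions of the same case on the same voxel grid. The auxiliaries are
#' typically the member predictions of a cross-validation ensemble, or
#' stochastic forward passes; their origin is recorded as free-form metadata
#' only, since all agreement metrics operate on the hard label maps.
#'
#' @slot final the final prediction, a [LabelMap-class].
#' @slot auxiliaries list of [LabelMap-class], length >= 2, same grid,
#'   spacing and scheme as \code{final}.
#' @slot sourceMeta free-form list of per-auxiliary metadata (informational).
#'
#' @seealso [computeMetricPanel()].
#' @export
setClass("EnsembleSet",
  representation(
    final = "LabelMap",
    auxiliaries = "list",
    sourceMeta = "list"
  ),
  prototype(sourceMeta = list())
)

setValidity("EnsembleSet", function(object) {
  msg <- character(0)
  if (length(object@auxiliaries) < 2L)
    msg <- c(msg, "an ensemble needs at least 2 auxiliary predictions")
  if (!all(vapply(object@auxiliaries, is, logical(1), class2 = "LabelMap")))
    return("auxiliaries must all be LabelMap objects")
  ref <- object@final
  for (i in seq_along(object@auxiliaries)) {
    a <- object@auxiliaries[[i]]
    if (!identical(dim(a@voxels), dim(ref@voxels)))
      msg <- c(msg, sprintf("auxiliary %d grid shape differs from final", i))
    if (!isTRUE(all.equal(a@spacing, ref@spacing)))
      msg <- c(msg, sprintf("auxiliary %d spacing differs from final", i))
    if (!identical(a@scheme@labelIds, ref@scheme@labelIds))
      msg <- c(msg, sprintf("auxiliary %d scheme differs from final", i))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EnsembleSet
#'
#' @param final the final prediction, a [LabelMap-class].
#' @param auxiliaries list of auxiliary [LabelMap-class] predictions (N >= 2).
#' @param sourceMeta optional list of per-auxiliary metadata.
#' @return An [EnsembleSet-class] object.
#' @export
EnsembleSet <- function(final, auxiliaries, sourceMeta = list()) {
  new("EnsembleSet", final = final, auxiliaries = auxiliaries,
      sourceMeta = sourceMeta)
}
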