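#' @rdname LabelMap-class
#' @export
setMethod("voxels", "LabelMap", function(x) x@voxels)

#' @rdname LabelMap-class
#' @export
setMethod("spacing", "LabelMap", function(x) x@spacing)

#' @rdname LabelMap-class
#' @export
setMethod("scheme", "LabelMap", function(x) x@scheme)

#' @rdname LabelMap-class
#' @export
setMethod("dim", "LabelMap", function(x) dim(x@voxels))

#' @rdname StructureScheme-class
#' @export
setMethod("labelIds", "StructureScheme", function(x) x@labelIds)

#' @rdname StructureScheme-class
#' @export
setMethod("labelNames", "StructureScheme", function(x) x@labelNames)

#' @rdname StructureScheme-class
#' @export
setMethod("structureClasses", "StructureScheme", function(x) x@structureClasses)

#' @rdname StructureScheme-class
#' @export
setMethod("length", "StructureScheme", function(x) length(x@labelIds))

#' @rdname EnsembleSet-class
#' @export
setMethod("finalPrediction", "EnsembleSet", function(x) x@final)

#' @rdname EnsembleSet-class
#' @export
setMethod("auxiliaries", "EnsembleSet", function(x) x@auxiliaries)

#' @rdname EnsembleSet-class
#' @export
setMethod("nAux", "EnsembleSet", function(x) length(x@auxiliaries))

#' @rdname LabelMap-class
#' @export
setMethod("binaryMask", "LabelMap", function(x, labelId) {
  labelId <- as.integer(labelId)
  if (!(labelId %in% c(x@scheme@labelIds, x@scheme@backgroundId)))
    stop(sprintf("label id %d is not in the scheme", labelId))
  x@voxels == labelId
})

setMethod("show", "StructureScheme", function(object) {
  cat(sprintf("StructureScheme with %d structures (background = %d)\n",
              length(object@labelIds), object@backgroundId))
  df <- data.frame(id = object@labelIds, name = object@labelNames,
                   class = object@structureClasses)
  print(df, row.names = FALSE)
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@voxels)
  fg <- labelVolumes(object)
  cat(sprintf("LabelMap %dx%dx%d voxels, spacing %s mm\n", d[1], d[2], d[3],
              paste(format(object@spacing, digits = 3), collapse = " x ")))
  cat(sprintf("  foreground: %s\n",
              paste(sprintf("%s=%d", names(fg), fg), collapse = ", ")))
})

setMethod("show", "EnsembleSet", function(object) {
  cat(sprintf("EnsembleSet: final prediction + %d auxiliaries on a %s grid\n",
              length(object@auxiliaries),
              paste(dim(object@final@voxels), collapse = "x")))
})

#' Per-label foreground voxel counts
#'
#' @param lm a [LabelMap-class].
#' @return Named integer vector of voxel counts, one per scheme label.
#' @export
labelVolumes <- function(lm) {
  stopifnot(is(lm, "LabelMap"))
  tab <- tabulate(lm@voxels + 1L, nbins = max(lm@scheme@labelIds) + 1L)
  out <- tab[lm@scheme@labelIds + 1L]
  names(out) <- lm@scheme@labelNames
  out
}
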