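#' Read a multi-label volume from NIfTI or NRRD
#'
#' Loads a 3D label volume, takes voxel spacing from the file header, and
#' validates every non-background voxel value against the scheme. Voxels
#' stored as floating point are accepted only when losslessly castable to
#' integers. Orientation/affine metadata beyond spacing is ignored: all
#' downstream metrics are voxel-set operations on a single shared grid.
#'
#' @param path a \code{.nii}, \code{.nii.gz} or \code{.nrrd} file.
#' @param scheme the [StructureScheme-class] to validate against.
#' @return A [LabelMap-class].
#' @seealso [writeLabelMap()]
#' @export
readLabelMap <- function(path, scheme = shoulderScheme()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    parsed <- readNrrd(path)
    vox <- parsed$data
    sp <- parsed$spacing
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    sp <- RNifti::pixdim(img)
    vox <- array(as.vector(img), dim = dim(img))
  } else {
    stop(sprintf("unsupported volume format: %s", path))
  }
  if (length(dim(vox)) > 3L)
    stop(sprintf("expected a 3D volume, got %d dimensions", length(dim(vox))))
  if (length(dim(vox)) < 3L) {
    # thin volumes with trailing singleton axes read back with fewer dims
    dim(vox) <- c(dim(vox), rep(1L, 3L - length(dim(vox))))
  }
  sp <- c(sp, rep(1, 3))[1:3]
  if (!is.integer(vox)) {
    if (any(vox != round(vox)))
      stop(sprintf("non-integer voxel values in %s", path))
    storage.mode(vox) <- "integer"
  }
  LabelMap(vox, spacing = sp, scheme = scheme)
}

#' Write a LabelMap to NIfTI or NRRD
#'
#' The on-disk file round-trips through [readLabelMap()] bit-exactly in the
#' voxel array and within float tolerance in the spacing.
#'
#' @param lm a [LabelMap-class].
#' @param path destination \code{.nii}, \code{.nii.gz} or \code{.nrrd} path;
#'   the parent directory must exist.
#' @return Invisibly, \code{path}.
#' @export
writeLabelMap <- function(lm, path) {
  stopifnot(is(lm, "LabelMap"))
  if (!dir.exists(dirname(path)))
    stop(sprintf("directory does not exist: %s", dirname(path)))
  if (grepl("\\.nrrd$", path, ignore.case = TRUE)) {
    writeNrrd(lm@voxels, lm@spacing, path)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(lm@voxels)
    RNifti::pixdim(img) <- lm@spacing
    RNifti::writeNifti(img, path)
  } else {
    stop(sprintf("unsupported volume format: %s", path))
  }
  invisible(path)
}

# Minimal NRRD codec for 3D integer label volumes (detached headers, text
# encodings and non-integer types are out of scope). Data are stored with the
# first axis fastest, matching R's column-major layout.
readNrrd <- function(path) {
  buf <- readBin(path, "raw", file.size(path))
  # header ends at the first empty line
  nl <- which(buf == as.raw(10L))
  hdr_end <- NA_integer_
  prev <- 0L
  for (p in nl) {
    if (p == prev + 1L || (p == prev + 2L && buf[p - 1L] == as.raw(13L))) {
      hdr_end <- p
      break
    }
    prev <- p
  }
  if (is.na(hdr_end)) stop(sprintf("malformed NRRD header in %s", path))
  hdr <- strsplit(rawToChar(buf[seq_len(hdr_end)]), "\r?\n")[[1]]
  if (!grepl("^NRRD", hdr[1])) stop(sprintf("not an NRRD file: %s", path))
  fields <- list()
  for (line in hdr[-1]) {
    if (line == "" || grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(kv) == 3L) fields[[tolower(trimws(kv[2]))]] <- trimws(kv[3])
  }
  dimn <- as.integer(fields[["dimension"]])
  if (!identical(dimn, 3L)) stop("only 3-dimensional NRRD volumes are supported")
  sizes <- as.integer(strsplit(fields[["sizes"]], "[ \t]+")[[1]])
  type <- tolower(fields[["type"]])
  spec <- switch(type,
    "int" = , "int32" = , "signed int" = list(what = "integer", size = 4L, signed = TRUE),
    "short" = , "int16" = , "signed short" = list(what = "integer", size = 2L, signed = TRUE),
    "uchar" = , "uint8" = , "unsigned char" = list(what = "integer", size = 1L, signed = FALSE),
    stop(sprintf("unsupported NRRD type: %s", type))
  )
  endian <- if (is.null(fields[["endian"]])) "little" else fields[["endian"]]
  enc <- tolower(fields[["encoding"]])
  payload <- buf[(hdr_end + 1L):length(buf)]
  if (enc %in% c("gz", "gzip")) {
    payload <- memDecompress(payload, type = "gzip")
  } else if (enc != "raw") {
    stop(sprintf("unsupported NRRD encoding: %s", enc))
  }
  vals <- readBin(payload, what = spec$what, n = prod(sizes),
                  size = spec$size, signed = spec$signed, endian = endian)
  if (length(vals) != prod(sizes))
    stop(sprintf("truncated NRRD data in %s", path))
  sp <- c(1, 1, 1)
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "[ \t]+")[[1]])
  } else if (!is.null(fields[["space directions"]])) {
    vecs <- regmatches(fields[["space directions"]],
                       gregexpr("\\(([^)]*)\\)", fields[["space directions"]]))[[1]]
    mat <- vapply(vecs, function(v) {
      as.numeric(strsplit(gsub("[()]", "", v), ",")[[1]])
    }, numeric(3))
    sp <- sqrt(colSums(mat^2))
  }
  list(data = array(vals, dim = sizes), spacing = sp)
}

writeNrrd <- function(vox, spacing, path) {
  hdr <- c(
    "NRRD0004",
    "type: int32",
    "dimension: 3",
    sprintf("sizes: %s", paste(dim(vox), collapse = " ")),
    sprintf("spacings: %s", paste(format(spacing, digits = 15), collapse = " ")),
    "endian: little",
    "encoding: raw",
    ""
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(paste(hdr, collapse = "\n"), "\n"), con, eos = NULL)
  writeBin(as.vector(vox), con, size = 4L, endian = "little")
  invisible(path)
}

#' Read a structure scheme from YAML or JSON
#'
#' Expects a mapping with a \code{structures} list of \code{{id, name, class}}
#' entries (and an optional \code{background} id), or a bare list of such
#' entries.
#'
#' @param path a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return A [StructureScheme-class].
#' @export
readScheme <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  bg <- 0L
  entries <- raw
  if (!is.null(raw$structures)) {
    entries <- raw$structures
    if (!is.null(raw$background)) bg <- as.integer(raw$background)
  }
  StructureScheme(
    labelIds = vapply(entries, function(e) as.integer(e$id), integer(1)),
    labelNames = vapply(entries, function(e) as.character(e$name), character(1)),
    structureClasses = vapply(entries, function(e) as.character(e$class), character(1)),
    backgroundId = bg
  )
}

#' Write a structure scheme to YAML
#'
#' @param scheme a [StructureScheme-class].
#' @param path destination \code{.yaml} path.
#' @return Invisibly, \code{path}.
#' @export
writeScheme <- function(scheme, path) {
  stopifnot(is(scheme, "StructureScheme"))
  entries <- lapply(seq_along(scheme@labelIds), function(i) {
    list(id = scheme@labelIds[i], name = scheme@labelNames[i],
         class = scheme@structureClasses[i])
  })
  yaml::write_yaml(list(background = scheme@backgroundId, structures = entries),
                   path)
  invisible(path)
}
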