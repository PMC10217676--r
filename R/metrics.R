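#' Dice coefficient between two binary masks
#'
#' \eqn{2|A \cap B| / (|A| + |B|)}. Two empty masks agree perfectly on the
#' absence of the structure and score 1; an empty versus a non-empty mask
#' scores 0.
#'
#' @param a,b logical arrays of identical shape.
#' @return A ratio in \[0, 1\].
#' @examples
#' a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
#' diceCoefficient(a, a)
#' @export
diceCoefficient <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask shapes differ")
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Intersection over union of the auxiliary predictions
#'
#' \eqn{|P_1 \cap \dots \cap P_N| / |P_1 \cup \dots \cup P_N|} over the
#' auxiliary masks of one label. When the union is empty every auxiliary
#' agrees the label is absent and the value is 1; [computeMetricPanel()]
#' additionally flags this situation so downstream classification can treat
#' it specially.
#'
#' @param masks list of >= 2 logical arrays of identical shape.
#' @return A ratio in \[0, 1\].
#' @export
iouAll <- function(masks) {
  checkMaskList(masks)
  uni <- sum(Reduce(`|`, masks))
  if (uni == 0) return(1)
  sum(Reduce(`&`, masks)) / uni
}

#' Intersection of the auxiliaries over the final prediction
#'
#' \eqn{|P_1 \cap \dots \cap P_N| / |P = l|}: the fraction of the final
#' prediction's mask covered by the voxels on which every auxiliary agrees.
#' Undefined (\code{NA}) when the final mask is empty. The auxiliary
#' intersection need not be a subset of the final mask, so values above 1 are
#' possible; they are reported unclamped and flagged by
#' [computeMetricPanel()].
#'
#' @param masks list of >= 2 auxiliary logical arrays.
#' @param finalMask logical array of the final prediction, same shape.
#' @return A non-negative ratio, or \code{NA} when the final mask is empty.
#' @export
intersectionOverPrediction <- function(masks, finalMask) {
  checkMaskList(masks)
  if (!identical(dim(masks[[1]]), dim(finalMask))) stop("mask shapes differ")
  nf <- sum(finalMask)
  if (nf == 0) return(NA_real_)
  sum(Reduce(`&`, masks)) / nf
}

#' Represent an overlap ratio as a Dice coefficient
#'
#' The monotone map \eqn{x \mapsto 2x/(1+x)}, which turns an IoU-type ratio
#' into the Dice coefficient of masks with that IoU. Fixes 0 and 1.
#'
#' @param x a non-negative ratio (NA passes through).
#' @return \code{2 * x / (1 + x)}.
#' @export
diceTransform <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("ratio must be non-negative")
  2 * x / (1 + x)
}

perAuxiliaryDices <- function(masks, finalMask) {
  vapply(masks, diceCoefficient, numeric(1), b = finalMask)
}

#' Average Dice between auxiliaries and the final prediction
#'
#' Arithmetic mean of the Dice coefficients between each auxiliary mask and
#' the final mask (the DCA metric).
#'
#' @inheritParams intersectionOverPrediction
#' @return A ratio in \[0, 1\].
#' @export
diceAverage <- function(masks, finalMask) {
  checkMaskList(masks)
  mean(perAuxiliaryDices(masks, finalMask))
}

#' Median Dice between auxiliaries and the final prediction
#'
#' Median of the per-auxiliary Dice coefficients (the DCM metric); for an
#' even number of auxiliaries, the mean of the two central order statistics.
#'
#' @inheritParams intersectionOverPrediction
#' @return A ratio in \[0, 1\].
#' @export
diceMedian <- function(masks, finalMask) {
  checkMaskList(masks)
  stats::median(perAuxiliaryDices(masks, finalMask))
}

#' Coefficient of variation of the auxiliary label volumes
#'
#' \eqn{\sigma/\mu} of the per-auxiliary foreground voxel counts. Volumes are
#' voxel counts: spacing is shared within an ensemble, so the physical volume
#' is a constant multiple and the ratio is unchanged. Undefined (\code{NA})
#' when every auxiliary mask is empty (\eqn{\mu = 0}).
#'
#' @param masks list of >= 2 logical arrays.
#' @param sd either \code{"sample"} (the default, \eqn{n - 1} denominator) or
#'   \code{"population"} (\eqn{n} denominator).
#' @return A non-negative ratio, or \code{NA}.
#' @export
volumeCV <- function(masks, sd = c("sample", "population")) {
  checkMaskList(masks)
  sd <- match.arg(sd)
  vols <- vapply(masks, sum, numeric(1))
  mu <- mean(vols)
  if (mu == 0) return(NA_real_)
  sigma <- stats::sd(vols)
  if (sd == "population")
    sigma <- sigma * sqrt((length(vols) - 1) / length(vols))
  sigma / mu
}

checkMaskList <- function(masks) {
  if (length(masks) < 2L)
    stop("at least 2 auxiliary masks are required")
  d <- dim(masks[[1]])
  for (m in masks[-1]) {
    if (!identical(dim(m), d)) stop("mask shapes differ")
  }
  invisible(TRUE)
}

#' Names and orientations of the seven agreement metrics
#'
#' All Dice-family metrics increase with agreement (\code{"higher_is_better"});
#' the volume coefficient of variation increases with disagreement
#' (\code{"lower_is_better"}).
#'
#' @return Named character vector mapping metric name to orientation.
#' @export
metricOrientations <- function() {
  c(IoU = "higher_is_better", IoP = "higher_is_better",
    DC_IoU = "higher_is_better", DC_IoP = "higher_is_better",
    DCA = "higher_is_better", DCM = "higher_is_better",
    CV = "lower_is_better")
}

#' Compute the seven-metric agreement panel of an ensemble
#'
#' For every foreground label of the scheme, computes IoU, IoP, their
#' Dice-transformed forms, the average and median per-auxiliary Dice, and the
#' volume coefficient of variation. Degenerate situations are reported as
#' \code{NA} plus an explicit flag, never silently zeroed:
#' \describe{
#'   \item{\code{all_empty}}{the label is absent from the final prediction and
#'     every auxiliary; all seven metrics are \code{NA}.}
#'   \item{\code{aux_all_empty}}{every auxiliary lacks the label (IoU
#'     conventionally 1, CV undefined).}
#'   \item{\code{final_empty}}{the final prediction lacks the label; IoP is
#'     undefined.}
#'   \item{\code{iop_over_one}}{the auxiliary intersection exceeds the final
#'     mask, so IoP > 1 (reported unclamped).}
#' }
#'
#' @param es an [EnsembleSet-class].
#' @param caseId identifier recorded in the \code{case_id} column.
#' @param cvSd passed to [volumeCV()].
#' @return A data.frame with one row per foreground label: \code{case_id},
#'   \code{label_id}, \code{label}, \code{n_aux}, the seven metric columns,
#'   and the four flag columns.
#' @export
computeMetricPanel <- function(es, caseId = "case", cvSd = "sample") {
  stopifnot(is(es, "EnsembleSet"))
  sch <- es@final@scheme
  rows <- lapply(seq_along(sch@labelIds), function(i) {
    l <- sch@labelIds[i]
    fm <- binaryMask(es@final, l)
    am <- lapply(es@auxiliaries, binaryMask, labelId = l)
    auxEmpty <- all(vapply(am, sum, numeric(1)) == 0)
    finalEmpty <- sum(fm) == 0
    allEmpty <- auxEmpty && finalEmpty
    if (allEmpty) {
      iou <- iop <- dca <- dcm <- cv <- NA_real_
    } else {
      iou <- iouAll(am)
      iop <- intersectionOverPrediction(am, fm)
      dca <- diceAverage(am, fm)
      dcm <- diceMedian(am, fm)
      cv <- volumeCV(am, sd = cvSd)
    }
    data.frame(
      case_id = caseId, label_id = l, label = sch@labelNames[i],
      n_aux = length(es@auxiliaries),
      IoU = iou, IoP = iop,
      DC_IoU = diceTransform(iou), DC_IoP = diceTransform(iop),
      DCA = dca, DCM = dcm, CV = cv,
      all_empty = allEmpty, aux_all_empty = auxEmpty,
      final_empty = finalEmpty,
      iop_over_one = !is.na(iop) && iop > 1,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Write or read a metric panel
#'
#' One row per (case, label) with all seven metrics, the auxiliary count and
#' the degeneracy flags, as CSV or JSON (chosen by file extension).
#'
#' @param panel a panel data.frame from [computeMetricPanel()] (rows of
#'   several cases may be \code{rbind}-ed together).
#' @param path destination/source \code{.csv} or \code{.json} path.
#' @return \code{writePanel} invisibly returns \code{path}; \code{readPanel}
#'   returns the panel data.frame.
#' @export
writePanel <- function(panel, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(panel, path, dataframe = "rows", digits = NA,
                         na = "null")
  } else {
    utils::write.csv(panel, path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname writePanel
#' @export
readPanel <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
}
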