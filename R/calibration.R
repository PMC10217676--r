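#' Label-wise extent of manual correction
#'
#' Quantifies how much an expert had to change a raw prediction, as the Dice
#' coefficient between the raw and the corrected segmentation for each label.
#' A label left untouched scores exactly 1; lower values mean more extensive
#' correction. This correction Dice is the ground truth for segmentation
#' accuracy used throughout calibration and evaluation.
#'
#' @param raw,corrected [LabelMap-class] objects on the same grid with the
#'   same scheme.
#' @param caseId identifier recorded in the \code{case_id} column.
#' @return A correction record: data.frame with columns \code{case_id},
#'   \code{label_id}, \code{label}, \code{correction_dice}.
#' @export
extentOfCorrection <- function(raw, corrected, caseId = "case") {
  stopifnot(is(raw, "LabelMap"), is(corrected, "LabelMap"))
  if (!identical(dim(raw@voxels), dim(corrected@voxels)))
    stop("raw and corrected grids differ")
  if (!identical(raw@scheme@labelIds, corrected@scheme@labelIds))
    stop("raw and corrected schemes differ")
  sch <- raw@scheme
  dice <- vapply(sch@labelIds, function(l) {
    diceCoefficient(binaryMask(raw, l), binaryMask(corrected, l))
  }, numeric(1))
  data.frame(case_id = caseId, label_id = sch@labelIds,
             label = sch@labelNames, correction_dice = dice,
             stringsAsFactors = FALSE)
}

#' Goodness rule: correction-Dice thresholds per structure class
#'
#' A segmentation of a label counts as insufficiently accurate when its
#' correction Dice falls strictly below the threshold of its structure class.
#' Bones carry a stricter default (0.975) than muscles (0.925): bone-derived
#' clinical measures rely on landmarks on the bone surface and are more
#' sensitive to boundary error than whole-muscle measures such as volume or
#' fat fraction. A correction Dice exactly at the threshold is sufficient.
#'
#' @param bone,muscle thresholds in (0, 1].
#' @return A \code{GoodnessRule} list.
#' @export
goodnessRule <- function(bone = 0.975, muscle = 0.925) {
  stopifnot(bone > 0, bone <= 1, muscle > 0, muscle <= 1)
  structure(list(bone = bone, muscle = muscle), class = "GoodnessRule")
}

#' Classify per-label correction extents into sufficient/insufficient
#'
#' Applies a [goodnessRule()] to a correction record: a label is
#' \code{"insufficient"} iff its correction Dice is strictly below its
#' structure class threshold (boundary counts as sufficient).
#'
#' @param record a correction record from [extentOfCorrection()] (rows of
#'   several cases may be combined).
#' @param rule a [goodnessRule()].
#' @param scheme the [StructureScheme-class] giving each label's class.
#' @return The record with an added \code{truth} column of
#'   \code{"sufficient"}/\code{"insufficient"}.
#' @export
goodnessTruth <- function(record, rule = goodnessRule(),
                          scheme = shoulderScheme()) {
  stopifnot(inherits(rule, "GoodnessRule"))
  missing <- setdiff(scheme@labelIds, unique(record$label_id))
  if (length(missing))
    stop(sprintf("labels missing from record: %s",
                 paste(missing, collapse = ", ")))
  cls <- scheme@structureClasses[match(record$label_id, scheme@labelIds)]
  if (anyNA(cls))
    stop("record contains labels not in the scheme")
  thr <- ifelse(cls == "bone", rule$bone, rule$muscle)
  record$truth <- ifelse(record$correction_dice < thr,
                         "insufficient", "sufficient")
  record
}

#' Coefficient of determination between metric and correction extent
#'
#' The squared Pearson correlation of the paired values. (For a simple linear
#' regression of one variable on the other this equals the regression R^2, so
#' the correlation and regression readings coincide.) Undefined (\code{NA})
#' when either variable is constant; pairs with missing values are dropped.
#'
#' @param metricValues,correctionDices equal-length numeric vectors with at
#'   least 3 complete pairs.
#' @return R^2 in \[0, 1\], or \code{NA} for degenerate input.
#' @export
coefficientOfDetermination <- function(metricValues, correctionDices) {
  if (length(metricValues) != length(correctionDices))
    stop("input lengths differ")
  ok <- !is.na(metricValues) & !is.na(correctionDices)
  x <- metricValues[ok]; y <- correctionDices[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

#' Rank agreement metrics by how well they predict correction extent
#'
#' For every metric of the panel, computes the coefficient of determination
#' against the correction Dice, pooled over all (case, label) instances with
#' defined metric values and also per label. Metrics are ranked by the pooled
#' value; constant (degenerate) metrics come out \code{NA} and sort last.
#'
#' @param panel a metric panel covering one or more cases
#'   ([computeMetricPanel()] rows combined).
#' @param records correction records covering the same cases
#'   ([extentOfCorrection()]).
#' @param metrics which metric columns to rank.
#' @return A data.frame with columns \code{metric}, \code{scope} (a label name
#'   or \code{"pooled"}), \code{r_squared} and \code{n}, ordered by pooled
#'   R^2 descending.
#' @export
rankMetrics <- function(panel, records, metrics = names(metricOrientations())) {
  merged <- merge(panel, records[, c("case_id", "label_id", "correction_dice")],
                  by = c("case_id", "label_id"))
  if (nrow(merged) == 0L) stop("no cases align between panel and records")
  scopes <- c("pooled", unique(merged$label))
  out <- do.call(rbind, lapply(metrics, function(m) {
    do.call(rbind, lapply(scopes, function(sc) {
      sub <- if (sc == "pooled") merged else merged[merged$label == sc, ]
      ok <- !is.na(sub[[m]]) & !is.na(sub$correction_dice)
      r2 <- if (sum(ok) >= 3L && stats::sd(sub[[m]][ok]) > 0 &&
                stats::sd(sub$correction_dice[ok]) > 0) {
        coefficientOfDetermination(sub[[m]][ok], sub$correction_dice[ok])
      } else NA_real_
      data.frame(metric = m, scope = sc, r_squared = r2, n = sum(ok),
                 stringsAsFactors = FALSE)
    }))
  }))
  pooled <- out[out$scope == "pooled", ]
  ord <- order(-replace(pooled$r_squared, is.na(pooled$r_squared), -Inf))
  out$metric <- factor(out$metric, levels = pooled$metric[ord])
  out <- out[order(out$metric, out$scope != "pooled", out$scope), ]
  out$metric <- as.character(out$metric)
  rownames(out) <- NULL
  out
}

#' Calibrate a classification threshold with a sensitivity-weighted Youden index
#'
#' Scans every candidate threshold (midpoints between adjacent distinct sorted
#' metric values, plus \code{-Inf}/\code{+Inf} sentinels) and returns the one
#' maximizing the generalized Youden objective \eqn{J_w = w \cdot Se + Sp},
#' where the positive class is \code{"insufficient"} — so sensitivity is the
#' detection rate of bad segmentations — and \eqn{w > 1} penalizes missed
#' detections more than false alarms (default \eqn{w = 2}). An instance is
#' predicted insufficient iff its metric value is strictly worse than the
#' threshold under the given orientation. Ties in \eqn{J_w} are broken toward
#' higher sensitivity, then toward the more conservative threshold (the one
#' flagging more aggressively).
#'
#' @param metricValues numeric vector of metric values (no NAs).
#' @param truth parallel vector of \code{"sufficient"}/\code{"insufficient"};
#'   both classes must be present.
#' @param weight relative loss of a missed detection, \eqn{w > 0}.
#' @param orientation \code{"higher_is_better"} (Dice-family metrics) or
#'   \code{"lower_is_better"} (volume CV).
#' @return A list with \code{threshold}, \code{sensitivity},
#'   \code{specificity} and \code{youden} (the achieved \eqn{J_w}).
#' @export
calibrateThreshold <- function(metricValues, truth, weight = 2,
                               orientation = c("higher_is_better",
                                               "lower_is_better")) {
  orientation <- match.arg(orientation)
  stopifnot(length(metricValues) == length(truth), weight > 0)
  if (anyNA(metricValues)) stop("metric values must not be missing")
  if (!all(truth %in% c("sufficient", "insufficient")))
    stop("truth must be 'sufficient' or 'insufficient'")
  pos <- truth == "insufficient"
  if (!any(pos) || all(pos))
    stop("both goodness classes must be present to calibrate a threshold")
  v <- sort(unique(metricValues))
  cand <- c(-Inf, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2, Inf)
  best <- NULL
  for (t in cand) {
    flagged <- if (orientation == "higher_is_better") metricValues < t
               else metricValues > t
    se <- sum(flagged & pos) / sum(pos)
    sp <- sum(!flagged & !pos) / sum(!pos)
    j <- weight * se + sp
    better <- is.null(best) || j > best$youden ||
      (j == best$youden && se > best$sensitivity) ||
      (j == best$youden && se == best$sensitivity &&
         ((orientation == "higher_is_better" && t > best$threshold) ||
          (orientation == "lower_is_better" && t < best$threshold)))
    if (better)
      best <- list(threshold = t, sensitivity = se, specificity = sp,
                   youden = j)
  }
  best
}

#' Calibrate label-specific thresholds over a cohort
#'
#' End-to-end calibration: derives the goodness truth from the correction
#' records, optionally selects the metric (the one with the best pooled R^2
#' against the correction Dice when \code{metric = NULL}), and calibrates one
#' threshold per label with [calibrateThreshold()]. Instances with undefined
#' metric values are excluded from calibration (at application time they are
#' flagged fail-safe by [classifyPanel()]).
#'
#' @param panel multi-case metric panel.
#' @param records multi-case correction records.
#' @param scheme the [StructureScheme-class].
#' @param rule the [goodnessRule()] defining truth.
#' @param metric a metric name, or \code{NULL} to pick the best-ranked one.
#' @param weight sensitivity weight of the Youden objective.
#' @return A calibration table: data.frame with one row per label
#'   (\code{label_id}, \code{label}, \code{metric}, \code{orientation},
#'   \code{threshold}, \code{r_squared}, \code{youden}, \code{sensitivity},
#'   \code{specificity}), with the weight stored in attribute
#'   \code{"sensitivity_weight"}.
#' @export
calibrateCohort <- function(panel, records, scheme = shoulderScheme(),
                            rule = goodnessRule(), metric = NULL, weight = 2) {
  records <- goodnessTruth(records, rule, scheme)
  if (is.null(metric)) {
    ranking <- rankMetrics(panel, records)
    metric <- ranking$metric[ranking$scope == "pooled"][1]
  }
  if (!metric %in% names(metricOrientations()))
    stop(sprintf("unknown metric: %s", metric))
  orientation <- unname(metricOrientations()[metric])
  merged <- merge(panel, records[, c("case_id", "label_id", "truth",
                                     "correction_dice")],
                  by = c("case_id", "label_id"))
  rows <- lapply(seq_along(scheme@labelIds), function(i) {
    l <- scheme@labelIds[i]
    sub <- merged[merged$label_id == l & !is.na(merged[[metric]]), ]
    if (length(unique(sub$truth)) < 2L)
      stop(sprintf("label %s has a single goodness class; cannot calibrate",
                   scheme@labelNames[i]))
    fit <- calibrateThreshold(sub[[metric]], sub$truth, weight = weight,
                              orientation = orientation)
    r2 <- tryCatch(coefficientOfDetermination(sub[[metric]],
                                              sub$correction_dice),
                   error = function(e) NA_real_)
    data.frame(label_id = l, label = scheme@labelNames[i], metric = metric,
               orientation = orientation, threshold = fit$threshold,
               r_squared = r2, youden = fit$youden,
               sensitivity = fit$sensitivity, specificity = fit$specificity,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "sensitivity_weight") <- weight
  out
}

#' Write or read a calibration table
#'
#' JSON round-trip of the calibration table of [calibrateCohort()], including
#' the sensitivity weight.
#'
#' @param calib a calibration table.
#' @param path a \code{.json} path.
#' @return \code{writeCalibration} invisibly returns \code{path};
#'   \code{readCalibration} returns the calibration table.
#' @export
writeCalibration <- function(calib, path) {
  payload <- list(sensitivity_weight = attr(calib, "sensitivity_weight"),
                  per_label = calib)
  jsonlite::write_json(payload, path, dataframe = "rows", digits = NA,
                       auto_unbox = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeCalibration
#' @export
readCalibration <- function(path) {
  payload <- jsonlite::fromJSON(path)
  out <- as.data.frame(payload$per_label)
  attr(out, "sensitivity_weight") <- payload$sensitivity_weight
  out
}
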