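#' Flag insufficiently accurate labels with calibrated thresholds
#'
#' Applies a calibration table to a metric panel: a (case, label) instance is
#' flagged \code{"insufficient"} iff its metric value is strictly worse than
#' the label's threshold under the metric's orientation (a value exactly at
#' the threshold is sufficient). Undefined metric values are flagged
#' insufficient fail-safe — a structure the ensemble cannot even agree exists
#' must go to a human, never silently pass.
#'
#' @param panel a metric panel covering one or more cases.
#' @param calib a calibration table from [calibrateCohort()],
#'   [readCalibration()] or [loadCalibrationPreset()].
#' @return A data.frame with one row per (case, label): \code{case_id},
#'   \code{label_id}, \code{label}, \code{metric}, \code{value},
#'   \code{threshold}, \code{flag}, \code{fail_safe}.
#' @export
classifyPanel <- function(panel, calib) {
  missing <- setdiff(unique(panel$label_id), calib$label_id)
  if (length(missing))
    stop(sprintf("no calibration for label id(s): %s",
                 paste(missing, collapse = ", ")))
  idx <- match(panel$label_id, calib$label_id)
  metric <- calib$metric[idx]
  value <- vapply(seq_len(nrow(panel)),
                  function(i) as.numeric(panel[i, metric[i]]), numeric(1))
  threshold <- calib$threshold[idx]
  orientation <- calib$orientation[idx]
  worse <- ifelse(orientation == "higher_is_better",
                  value < threshold, value > threshold)
  failSafe <- is.na(value)
  flag <- ifelse(failSafe | worse, "insufficient", "sufficient")
  data.frame(case_id = panel$case_id, label_id = panel$label_id,
             label = panel$label, metric = metric, value = value,
             threshold = threshold, flag = flag, fail_safe = failSafe,
             stringsAsFactors = FALSE)
}

roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Evaluate goodness flags against correction-based truth
#'
#' Compares automatic flags with the truth defined by the extent of manual
#' correction, instance by instance (positive class = insufficient). Reports
#' per-label confusion counts and sensitivity/specificity, the pooled values
#' over all instances (\eqn{Se = \Sigma TP / \Sigma(TP + FN)}, \eqn{Sp =
#' \Sigma TN / \Sigma(TN + FP)}), and the macro averages (unweighted mean of
#' per-label values); pooled and macro agree when per-label instance counts
#' are equal. Values are kept at full precision; the print method rounds
#' half-up to 2 decimals.
#'
#' @param flags data.frame with \code{case_id}, \code{label_id}, \code{label},
#'   \code{flag} (from [classifyPanel()]), optionally \code{threshold}.
#' @param truth data.frame with \code{case_id}, \code{label_id}, \code{truth}
#'   (from [goodnessTruth()]).
#' @return A \code{QCReport} list: \code{per_label} data.frame (confusion
#'   counts, sensitivity, specificity, threshold when available),
#'   \code{pooled} and \code{macro} sensitivity/specificity,
#'   \code{flagged_fraction}, \code{n_instances}.
#' @export
evaluateClassification <- function(flags, truth) {
  merged <- merge(flags, truth[, c("case_id", "label_id", "truth")],
                  by = c("case_id", "label_id"))
  if (nrow(merged) < nrow(flags) || nrow(merged) < nrow(truth))
    stop("flags and truth cohorts are not aligned by (case_id, label_id)")
  pos <- merged$truth == "insufficient"
  hit <- merged$flag == "insufficient"
  perLabel <- do.call(rbind, lapply(split(seq_len(nrow(merged)),
                                          merged$label_id), function(ix) {
    tp <- sum(hit[ix] & pos[ix]);  fn <- sum(!hit[ix] & pos[ix])
    fp <- sum(hit[ix] & !pos[ix]); tn <- sum(!hit[ix] & !pos[ix])
    data.frame(
      label_id = merged$label_id[ix[1]], label = merged$label[ix[1]],
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      TP = tp, TN = tn, FP = fp, FN = fn,
      threshold = if ("threshold" %in% names(merged))
        merged$threshold[ix[1]] else NA_real_,
      stringsAsFactors = FALSE)
  }))
  perLabel <- perLabel[order(perLabel$label_id), ]
  rownames(perLabel) <- NULL
  pooled <- list(
    sensitivity = if (sum(pos) > 0) sum(hit & pos) / sum(pos) else NA_real_,
    specificity = if (sum(!pos) > 0) sum(!hit & !pos) / sum(!pos) else NA_real_
  )
  macro <- list(sensitivity = mean(perLabel$sensitivity, na.rm = TRUE),
                specificity = mean(perLabel$specificity, na.rm = TRUE))
  structure(list(per_label = perLabel, pooled = pooled, macro = macro,
                 flagged_fraction = mean(hit), n_instances = nrow(merged)),
            class = "QCReport")
}

#' @export
print.QCReport <- function(x, ...) {
  cat(sprintf("QC report over %d (case, label) instances\n", x$n_instances))
  df <- x$per_label
  df$sensitivity <- roundHalfUp(df$sensitivity)
  df$specificity <- roundHalfUp(df$specificity)
  print(df, row.names = FALSE)
  cat(sprintf("pooled: Se %.2f, Sp %.2f | macro: Se %.2f, Sp %.2f | flagged %.1f%%\n",
              roundHalfUp(x$pooled$sensitivity),
              roundHalfUp(x$pooled$specificity),
              roundHalfUp(x$macro$sensitivity),
              roundHalfUp(x$macro$specificity),
              100 * x$flagged_fraction))
  invisible(x)
}

#' Fraction of labels needing correction in a cohort
#'
#' @param truth a truth cohort from [goodnessTruth()] (multi-case rows).
#' @return A list with \code{n_insufficient}, \code{n_total} and
#'   \code{percent} (0–100).
#' @export
summarizeFlagRate <- function(truth) {
  if (is.null(truth$truth) || nrow(truth) == 0L)
    stop("empty truth cohort")
  n <- nrow(truth)
  k <- sum(truth$truth == "insufficient")
  list(n_insufficient = k, n_total = n, percent = 100 * k / n)
}

#' Expand per-label confusion counts into an aligned instance cohort
#'
#' Reconstructs one minimal (flags, truth) cohort consistent with a table of
#' per-label confusion counts, so published confusion tables can be replayed
#' through [evaluateClassification()].
#'
#' @param counts data.frame with columns \code{label} (or \code{label_id}),
#'   \code{TP}, \code{TN}, \code{FP}, \code{FN}, optionally \code{threshold}.
#' @return A list of aligned \code{flags} and \code{truth} data.frames.
#' @export
expandConfusionCounts <- function(counts) {
  if (is.null(counts$label_id)) counts$label_id <- seq_len(nrow(counts))
  if (is.null(counts$label)) counts$label <- as.character(counts$label_id)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    r <- counts[i, ]
    fl <- c(rep("insufficient", r$TP), rep("sufficient", r$TN),
            rep("insufficient", r$FP), rep("sufficient", r$FN))
    tr <- c(rep("insufficient", r$TP), rep("sufficient", r$TN),
            rep("sufficient", r$FP), rep("insufficient", r$FN))
    data.frame(case_id = sprintf("case%03d", seq_along(fl)),
               label_id = r$label_id, label = r$label, flag = fl, truth = tr,
               threshold = if ("threshold" %in% names(counts))
                 r$threshold else NA_real_,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, rows)
  list(flags = all[, c("case_id", "label_id", "label", "flag", "threshold")],
       truth = all[, c("case_id", "label_id", "label", "truth")])
}

#' Shipped calibration presets
#'
#' \code{"shoulder_dca"} is the reference calibration of the average-Dice
#' (DCA) detector for the default shoulder scheme: the label-specific DCA
#' thresholds calibrated on a 51-volume shoulder MRI cohort (humerus 0.97,
#' scapula 0.94, SSP 0.92, SSC 0.91, ISP 0.93, TM 0.94).
#'
#' @param name preset name.
#' @return A calibration table usable with [classifyPanel()].
#' @export
loadCalibrationPreset <- function(name = "shoulder_dca") {
  path <- system.file("extdata", paste0(name, "_preset.json"),
                      package = "SegEnsembleQC")
  if (path == "") stop(sprintf("unknown preset: %s", name))
  readCalibration(path)
}
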