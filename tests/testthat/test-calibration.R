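test_that("extent of correction reflects hand-counted edits", {
  raw <- tinyLabelMap(c(3, 3, 3, 3, 3, 0, 1, 2, 0))
  expect_equal(extentOfCorrection(raw, raw)$correction_dice, rep(1, 6))
  # expert removes one of the five SSP voxels
  corr <- tinyLabelMap(c(3, 3, 3, 3, 0, 0, 1, 2, 0))
  rec <- extentOfCorrection(raw, corr)
  expect_equal(rec$correction_dice[rec$label == "supraspinatus"], 8 / 9)
  expect_equal(rec$correction_dice[rec$label == "humerus"], 1)
  # expert deletes the structure entirely
  gone <- tinyLabelMap(c(0, 0, 0, 0, 0, 0, 1, 2, 0))
  expect_equal(extentOfCorrection(raw, gone)$correction_dice[3], 0)
  other <- tinyLabelMap(rep(0, 16), dims = c(4, 4, 1))
  expect_error(extentOfCorrection(raw, other), "grids differ")
})

test_that("goodness truth applies class thresholds with a sufficient boundary", {
  rec <- data.frame(case_id = "c", label_id = 1:6,
                    label = labelNames(shoulderScheme()),
                    correction_dice = c(0.98, 0.975, 0.90, 0.925, 0.97, 0.80))
  truth <- goodnessTruth(rec, goodnessRule(), shoulderScheme())
  expect_equal(truth$truth,
               c("sufficient",    # bone 0.98 >= 0.975
                 "sufficient",    # bone exactly at threshold
                 "insufficient",  # muscle 0.90 < 0.925
                 "sufficient",    # muscle exactly at threshold
                 "sufficient", "insufficient"))
  expect_error(goodnessTruth(rec[-1, ], goodnessRule(), shoulderScheme()),
               "missing")
})

test_that("goodness truth is monotone in the correction dice", {
  set.seed(11)
  sch <- shoulderScheme()
  for (i in 1:50) {
    d <- runif(6, 0.6, 1)
    rec <- data.frame(case_id = "c", label_id = 1:6,
                      label = labelNames(sch), correction_dice = d)
    worse <- rec
    worse$correction_dice <- pmax(0, d - runif(6, 0, 0.3))
    t1 <- goodnessTruth(rec, goodnessRule(), sch)$truth
    t2 <- goodnessTruth(worse, goodnessRule(), sch)$truth
    # lowering the dice can only move sufficient -> insufficient
    expect_false(any(t1 == "insufficient" & t2 == "sufficient"))
  }
})

test_that("coefficient of determination is squared correlation with its edge cases", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(coefficientOfDetermination(x, 2 * x - 1), 1)
  expect_equal(coefficientOfDetermination(x, -3 * x + 10), 1)
  set.seed(202)
  a <- rnorm(1000); b <- rnorm(1000) # independent pairs
  expect_lt(coefficientOfDetermination(a, b), 0.01)
  # invariant to affine rescaling of either variable
  expect_equal(coefficientOfDetermination(10 * a + 3, b),
               coefficientOfDetermination(a, b))
  expect_true(is.na(coefficientOfDetermination(rep(1, 5), x)))
  expect_error(coefficientOfDetermination(1:2, 1:2), "at least 3")
})

test_that("metric ranking puts a perfect predictor first and drops constants", {
  set.seed(33)
  n <- 30
  dice <- runif(n, 0.7, 1)
  panel <- data.frame(case_id = sprintf("c%02d", seq_len(n)), label_id = 1,
                      label = "humerus", n_aux = 5,
                      IoU = dice,                  # identical to the target
                      IoP = runif(n),              # pure noise
                      DC_IoU = rep(0.5, n),        # constant -> undefined
                      DC_IoP = dice + rnorm(n, sd = 0.02),
                      DCA = dice + rnorm(n, sd = 0.1),
                      DCM = runif(n), CV = runif(n))
  records <- data.frame(case_id = panel$case_id, label_id = 1,
                        label = "humerus", correction_dice = dice)
  rk <- rankMetrics(panel, records)
  pooled <- rk[rk$scope == "pooled", ]
  expect_equal(pooled$metric[1], "IoU")
  expect_equal(pooled$r_squared[1], 1)
  expect_true(is.na(pooled$r_squared[pooled$metric == "DC_IoU"]))
  expect_gt(pooled$r_squared[pooled$metric == "DC_IoP"],
            pooled$r_squared[pooled$metric == "IoP"])
  expect_error(rankMetrics(panel, records[0, ]), "align")
})

test_that("threshold calibration solves the separable textbook case", {
  values <- c(0.99, 0.98, 0.90, 0.85)
  truth <- c("sufficient", "sufficient", "insufficient", "insufficient")
  fit <- calibrateThreshold(values, truth, weight = 2,
                            orientation = "higher_is_better")
  expect_equal(fit$threshold, 0.94) # midpoint of the separating gap
  expect_equal(fit$sensitivity, 1)
  expect_equal(fit$specificity, 1)
  expect_equal(fit$youden, 3)
  expect_error(calibrateThreshold(values, rep("sufficient", 4)),
               "both goodness classes")
})

test_that("calibration equals the exhaustive scan on random small inputs", {
  set.seed(505)
  for (rep in 1:120) {
    n <- sample(4:20, 1)
    values <- round(runif(n, 0.5, 1), sample(1:3, 1)) # ties are likely
    truth <- ifelse(runif(n) < 0.4, "insufficient", "sufficient")
    if (length(unique(truth)) < 2) next
    w <- sample(c(1, 2, 5), 1)
    orient <- sample(c("higher_is_better", "lower_is_better"), 1)
    fit <- calibrateThreshold(values, truth, weight = w, orientation = orient)
    ref <- oracleThreshold(values, truth, w, orient)
    expect_equal(fit$threshold, ref$threshold)
    expect_equal(fit$sensitivity, ref$se)
    expect_equal(fit$specificity, ref$sp)
  }
})

test_that("achieved operating point is invariant under monotone relabeling", {
  set.seed(77)
  values <- runif(30, 0.6, 1)
  truth <- ifelse(values < 0.8 | runif(30) < 0.1, "insufficient", "sufficient")
  if (length(unique(truth)) == 2) {
    f1 <- calibrateThreshold(values, truth)
    f2 <- calibrateThreshold(values^3, truth) # strictly increasing transform
    expect_equal(f1$sensitivity, f2$sensitivity)
    expect_equal(f1$specificity, f2$specificity)
  }
})

test_that("a large sensitivity weight forces full detection when achievable", {
  set.seed(88)
  values <- runif(40)
  truth <- ifelse(runif(40) < 0.3, "insufficient", "sufficient")
  fit <- calibrateThreshold(values, truth, weight = 1e6,
                            orientation = "higher_is_better")
  expect_equal(fit$sensitivity, 1)
})

test_that("cohort calibration recovers thresholds on a separable synthetic cohort", {
  set.seed(9)
  n <- 40
  sch <- shoulderScheme()
  # construct a cohort whose DCA mirrors the correction dice exactly
  dice <- runif(n, 0.75, 1)
  panel <- do.call(rbind, lapply(1:6, function(l) {
    data.frame(case_id = sprintf("c%02d", 1:n), label_id = l,
               label = labelNames(sch)[l], n_aux = 5,
               IoU = dice, IoP = dice, DC_IoU = dice, DC_IoP = dice,
               DCA = dice, DCM = dice, CV = 1 - dice)
  }))
  records <- do.call(rbind, lapply(1:6, function(l) {
    data.frame(case_id = sprintf("c%02d", 1:n), label_id = l,
               label = labelNames(sch)[l], correction_dice = dice)
  }))
  calib <- calibrateCohort(panel, records, metric = "DCA")
  expect_equal(calib$sensitivity, rep(1, 6))
  expect_equal(calib$specificity, rep(1, 6))
  # the recovered DCA threshold brackets the class threshold of each tissue
  expect_true(all(abs(calib$threshold - c(0.975, 0.975, rep(0.925, 4))) < 0.02))
  f <- tempfile(fileext = ".json")
  writeCalibration(calib, f)
  back <- readCalibration(f)
  expect_equal(back$threshold, calib$threshold, tolerance = 1e-12)
  expect_equal(attr(back, "sensitivity_weight"), 2)
})
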