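# Hand-computable fixtures on a 3x3x1 grid: mask of the first n cells.
firstN <- function(n, dims = c(3, 3, 1)) {
  array(seq_len(prod(dims)) <= n, dims)
}

test_that("dice coefficient matches hand counts and empty-mask conventions", {
  a <- firstN(4)
  b <- array(c(FALSE, rep(TRUE, 6), FALSE, FALSE), c(3, 3, 1)) # cells 2..7
  # |a| = 4, |b| = 6, |a ∩ b| = 3 -> 2*3/10
  expect_equal(diceCoefficient(a, b), 0.6)
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(firstN(3), !firstN(3)), 0)
  expect_equal(diceCoefficient(firstN(0), firstN(0)), 1)
  expect_equal(diceCoefficient(firstN(0), firstN(2)), 0)
  expect_error(diceCoefficient(firstN(2), firstN(2, c(3, 1, 3))), "shape")
})

test_that("ensemble IoU matches enumeration on a constructed 2x2x2 instance", {
  m1 <- array(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE), c(2, 2, 2))
  m2 <- array(c(TRUE, TRUE, FALSE, FALSE, TRUE, TRUE, TRUE, FALSE), c(2, 2, 2))
  m3 <- array(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE), c(2, 2, 2))
  # intersection {1,2}, union {1..8} -> 2/8
  expect_equal(iouAll(list(m1, m2, m3)), 0.25)
  expect_equal(iouAll(list(m1, m1, m1)), 1)
  expect_equal(iouAll(list(firstN(2), !firstN(2))), 0)
  expect_equal(iouAll(list(firstN(0), firstN(0))), 1) # all agree on absence
  expect_error(iouAll(list(m1)), "at least 2")
})

test_that("n-way IoU never exceeds any pairwise IoU", {
  set.seed(41)
  for (rep in 1:25) {
    masks <- lapply(1:4, function(i) randomMask(c(4, 4, 4)))
    pairMin <- min(apply(utils::combn(4, 2), 2, function(ix)
      iouAll(masks[ix])))
    expect_lte(iouAll(masks), pairMin)
  }
})

test_that("intersection over prediction handles hand counts, undefined and >1 cases", {
  expect_equal(intersectionOverPrediction(list(firstN(3), firstN(3)), firstN(4)),
               0.75)
  expect_equal(intersectionOverPrediction(list(firstN(4), firstN(4)), firstN(4)),
               1)
  expect_equal(intersectionOverPrediction(list(firstN(2), !firstN(2)), firstN(3)),
               0)
  expect_true(is.na(intersectionOverPrediction(list(firstN(2), firstN(2)),
                                               firstN(0))))
  # auxiliary agreement larger than the final mask: unclamped value above 1
  expect_equal(intersectionOverPrediction(list(firstN(6), firstN(6)), firstN(3)),
               2)
})

test_that("the Dice transform is the exact bridge from IoU-type ratios", {
  expect_equal(diceTransform(0), 0)
  expect_equal(diceTransform(1), 1)
  expect_equal(diceTransform(1 / 3), 0.5)
  expect_error(diceTransform(-0.1), "non-negative")
  x <- seq(0, 1, by = 0.01)
  expect_true(all(diff(diceTransform(x)) > 0)) # strictly monotone
})

test_that("average and median auxiliary Dice follow their conventions", {
  f <- firstN(4)
  b <- array(c(FALSE, rep(TRUE, 6), FALSE, FALSE), c(3, 3, 1))
  # per-auxiliary Dices 0.6 and 1.0
  expect_equal(diceAverage(list(b, f), f), 0.8)
  expect_equal(diceMedian(list(b, f), f), 0.8) # even N: mean of central pair
  expect_equal(diceAverage(list(f, f, f), f), 1)
  masks5 <- list(f, f, f, b, b)
  d5 <- sort(vapply(masks5, diceCoefficient, numeric(1), b = f))
  expect_equal(diceMedian(masks5, f), d5[3])
  expect_equal(diceMedian(masks5, f), 1) # {1,1,1,0.6,0.6} -> middle is 1
  perm <- list(b, f, f, b, f)
  expect_equal(diceAverage(perm, f), diceAverage(masks5, f))
})

test_that("volume CV uses the sample standard deviation and is scale-free", {
  masks <- lapply(c(90, 100, 110), firstN, dims = c(12, 12, 1))
  expect_equal(volumeCV(masks), 0.1) # sample sd 10, mean 100
  expect_equal(volumeCV(masks, sd = "population"),
               sqrt(200 / 3) / 100)
  doubled <- lapply(c(90, 100, 110) * 2, firstN, dims = c(15, 15, 1))
  expect_equal(volumeCV(doubled), volumeCV(masks))
  expect_equal(volumeCV(list(firstN(5), firstN(5))), 0)
  expect_true(is.na(volumeCV(list(firstN(0), firstN(0)))))
})

test_that("a perfect ensemble yields a perfect panel", {
  lm <- tinyLabelMap(c(1, 1, 2, 2, 3, 4, 5, 6, 0))
  es <- EnsembleSet(lm, list(lm, lm, lm))
  panel <- computeMetricPanel(es, caseId = "perfect")
  expect_equal(nrow(panel), 6)
  for (m in c("IoU", "IoP", "DC_IoU", "DC_IoP", "DCA", "DCM"))
    expect_equal(panel[[m]], rep(1, 6), label = m)
  expect_equal(panel$CV, rep(0, 6))
  expect_false(any(panel$all_empty))
})

test_that("labels absent everywhere are flagged undefined, not zeroed", {
  lm <- tinyLabelMap(c(1, 1, 2, 2, 3, 4, 5, 0, 0)) # no teres minor anywhere
  es <- EnsembleSet(lm, list(lm, lm))
  panel <- computeMetricPanel(es)
  tm <- panel[panel$label == "teres_minor", ]
  expect_true(tm$all_empty)
  expect_true(all(is.na(tm[, c("IoU", "IoP", "DC_IoU", "DC_IoP",
                               "DCA", "DCM", "CV")])))
  # label present in auxiliaries but not the final: IoP undefined, flagged
  lmNoTm <- lm
  lmTm <- tinyLabelMap(c(1, 1, 2, 2, 3, 4, 5, 6, 0))
  es2 <- EnsembleSet(lmNoTm, list(lmTm, lmTm))
  p2 <- computeMetricPanel(es2)
  tm2 <- p2[p2$label == "teres_minor", ]
  expect_true(tm2$final_empty)
  expect_true(is.na(tm2$IoP))
  expect_equal(tm2$DCA, 0)
})

test_that("panels agree exactly with the voxel-enumeration oracle on random masks", {
  set.seed(90125)
  for (rep in 1:200) {
    dims <- sample(2:6, 3, replace = TRUE)
    n <- sample(2:5, 1)
    masks <- lapply(seq_len(n), function(i) randomMask(dims, p = runif(1, 0.1, 0.7)))
    fm <- randomMask(dims, p = 0.4)
    expect_identical(iouAll(masks), oracleIoU(masks))
    expect_identical(intersectionOverPrediction(masks, fm), oracleIoP(masks, fm))
    expect_equal(diceAverage(masks, fm), oracleDCA(masks, fm), tolerance = 1e-15)
    expect_equal(diceMedian(masks, fm), oracleDCM(masks, fm), tolerance = 1e-15)
    expect_equal(volumeCV(masks), oracleCV(masks), tolerance = 1e-15)
  }
})

test_that("the Dice-transformed metrics are consistent on every panel row", {
  gt <- smallPhantom(seed = 3)
  sim <- simulateCase(gt, degradationSpec(1.5, seed = 8))
  panel <- computeMetricPanel(sim$ensemble)
  expect_equal(panel$DC_IoU, 2 * panel$IoU / (1 + panel$IoU))
  expect_equal(panel$DC_IoP, 2 * panel$IoP / (1 + panel$IoP))
})

test_that("panel export round-trips through CSV and JSON", {
  gt <- smallPhantom(seed = 5)
  sim <- simulateCase(gt, degradationSpec(1, seed = 2))
  panel <- computeMetricPanel(sim$ensemble, caseId = "c1")
  for (ext in c(".csv", ".json")) {
    f <- tempfile(fileext = ext)
    writePanel(panel, f)
    back <- readPanel(f)
    expect_equal(back$DCA, panel$DCA, tolerance = 1e-12, label = ext)
    expect_equal(back$case_id, panel$case_id)
  }
})
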