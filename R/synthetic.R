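## Synthetic phantoms and degraded prediction ensembles.
##
## The generator emulates a cohort of cases whose ensemble members disagree in
## proportion to an underlying per-label accuracy, so the calibration and
## classification pipeline can be exercised end to end without clinical data.
## Degradation is morphological (partial boundary erosion/dilation, seeded
## patch dropout, near-interface label swaps), matching the failure modes seen
## in practice: boundary error, wholesale regional label loss, and
## artifact-driven mislabeling.

withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

shift3 <- function(m, dx, dy, dz) {
  d <- dim(m)
  out <- array(FALSE, d)
  xt <- max(1L, 1L + dx):min(d[1], d[1] + dx)
  yt <- max(1L, 1L + dy):min(d[2], d[2] + dy)
  zt <- max(1L, 1L + dz):min(d[3], d[3] + dz)
  out[xt, yt, zt] <- m[xt - dx, yt - dy, zt - dz]
  out
}

dilate6 <- function(m) {
  m | shift3(m, 1L, 0L, 0L) | shift3(m, -1L, 0L, 0L) |
      shift3(m, 0L, 1L, 0L) | shift3(m, 0L, -1L, 0L) |
      shift3(m, 0L, 0L, 1L) | shift3(m, 0L, 0L, -1L)
}

erode6 <- function(m) {
  m & shift3(m, 1L, 0L, 0L) & shift3(m, -1L, 0L, 0L) &
      shift3(m, 0L, 1L, 0L) & shift3(m, 0L, -1L, 0L) &
      shift3(m, 0L, 0L, 1L) & shift3(m, 0L, 0L, -1L)
}

defaultGeometry <- function() {
  list(
    list(kind = "ellipsoid", center = c(0.31, 0.50, 0.47),
         radii = c(0.19, 0.17, 0.17)),
    list(kind = "ellipsoid", center = c(0.70, 0.47, 0.47),
         radii = c(0.078, 0.23, 0.20)),
    list(kind = "capsule", p0 = c(0.47, 0.78, 0.22),
         p1 = c(0.75, 0.78, 0.53), radius = 0.070),
    list(kind = "capsule", p0 = c(0.25, 0.19, 0.31),
         p1 = c(0.62, 0.19, 0.69), radius = 0.070),
    list(kind = "capsule", p0 = c(0.25, 0.44, 0.81),
         p1 = c(0.69, 0.62, 0.81), radius = 0.062),
    list(kind = "capsule", p0 = c(0.38, 0.31, 0.125),
         p1 = c(0.62, 0.44, 0.125), radius = 0.047)
  )
}

#' Specification of a multi-structure 3D phantom
#'
#' Describes a deterministic (seeded) phantom with two bone-like compact
#' ellipsoids and four muscle-like elongated capsules, one structure per
#' scheme label, mimicking the topology and size ordering of the shoulder:
#' bones larger than muscles, teres minor the smallest muscle. Geometry is
#' given in grid-normalized coordinates so the same spec scales to any grid
#' size; structures are rasterized in label order and never overwrite one
#' another.
#'
#' @param gridShape three positive integers (default 64^3).
#' @param spacing voxel spacing in mm.
#' @param scheme a [StructureScheme-class]; geometry must supply one entry per
#'   scheme label.
#' @param geometry list of per-structure geometry entries (\code{kind}
#'   \code{"ellipsoid"} with \code{center}, \code{radii}, or \code{"capsule"}
#'   with \code{p0}, \code{p1}, \code{radius}), in normalized coordinates.
#' @param jitterVox seeded uniform jitter (voxels) applied to structure
#'   positions, emulating anatomical variability between cases.
#' @param seed integer seed making the phantom deterministic.
#' @return A \code{PhantomSpec} list.
#' @export
phantomSpec <- function(gridShape = c(64, 64, 64), spacing = c(1, 1, 1),
                        scheme = shoulderScheme(), geometry = defaultGeometry(),
                        jitterVox = 2, seed = 1) {
  stopifnot(length(gridShape) == 3, all(gridShape >= 16),
            length(geometry) == length(scheme@labelIds))
  structure(list(gridShape = as.integer(gridShape), spacing = spacing,
                 scheme = scheme, geometry = geometry, jitterVox = jitterVox,
                 seed = as.integer(seed)),
            class = "PhantomSpec")
}

#' Rasterize a phantom into a LabelMap
#'
#' Deterministic given the spec's seed. Every scheme label is guaranteed
#' present; an error is raised if jittered geometry leaves any structure
#' empty (geometry that cannot fit the grid).
#'
#' @param spec a [phantomSpec()].
#' @return A [LabelMap-class] ground-truth phantom.
#' @export
makePhantom <- function(spec) {
  stopifnot(inherits(spec, "PhantomSpec"))
  d <- spec$gridShape
  withSeed(spec$seed, {
    jit <- matrix(stats::runif(3 * length(spec$geometry), -spec$jitterVox,
                               spec$jitterVox), nrow = 3)
    x <- seq_len(d[1]); y <- seq_len(d[2]); z <- seq_len(d[3])
    X <- array(rep(x, times = d[2] * d[3]), d)
    Y <- array(rep(rep(y, each = d[1]), times = d[3]), d)
    Z <- array(rep(z, each = d[1] * d[2]), d)
    v <- array(0L, d)
    for (i in seq_along(spec$geometry)) {
      g <- spec$geometry[[i]]
      l <- spec$scheme@labelIds[i]
      inside <- if (g$kind == "ellipsoid") {
        ctr <- g$center * d + jit[, i]
        r <- g$radii * d
        ((X - ctr[1]) / r[1])^2 + ((Y - ctr[2]) / r[2])^2 +
          ((Z - ctr[3]) / r[3])^2 <= 1
      } else if (g$kind == "capsule") {
        p0 <- g$p0 * d + jit[, i]
        p1 <- g$p1 * d + jit[, i]
        dv <- p1 - p0
        L2 <- sum(dv^2)
        t <- ((X - p0[1]) * dv[1] + (Y - p0[2]) * dv[2] +
                (Z - p0[3]) * dv[3]) / L2
        t <- pmin(pmax(t, 0), 1)
        r <- g$radius * mean(d)
        (X - p0[1] - t * dv[1])^2 + (Y - p0[2] - t * dv[2])^2 +
          (Z - p0[3] - t * dv[3])^2 <= r^2
      } else stop(sprintf("unknown geometry kind: %s", g$kind))
      sel <- inside & v == 0L
      if (!any(sel))
        stop(sprintf("structure %s does not fit the grid",
                     spec$scheme@labelNames[i]))
      v[sel] <- l
    }
    LabelMap(v, spacing = spec$spacing, scheme = spec$scheme)
  })
}

sevString <- function(s) paste(format(s, trim = TRUE, digits = 6),
                               collapse = ";")

# Relabel the ball of radius r around voxel index (i, j, k): voxels of
# `from` become `to` (used both to drop a patch to background and to add a
# spurious patch onto background).
swapPatch <- function(v, center, r, from, to) {
  d <- dim(v)
  lo <- pmax(center - ceiling(r), 1L)
  hi <- pmin(center + ceiling(r), d)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  box <- v[xs, ys, zs, drop = FALSE]
  dist2 <- outer(outer((xs - center[1])^2, (ys - center[2])^2, `+`),
                 (zs - center[3])^2, `+`)
  box[dist2 <= r^2 & box == from] <- to
  v[xs, ys, zs] <- box
  v
}

#' Morphologically degrade a label map
#'
#' Applies seeded, label-wise perturbations whose expected Dice to the input
#' decreases strictly with \code{severity}; severity 0 is the identity. Three
#' operators act on each label: (1) coherent boundary noise — a
#' severity-scaled budget of flips, proportional to the surface of an
#' equivalent smooth shape (volume^(2/3)), is spent carving small dents
#' around random surface seeds and adding small bumps around random shell
#' seeds; (2) symmetric patch noise — with
#' probability growing with severity, a random surface patch (a ball sized
#' as a fraction of the structure volume) is lost to background, and,
#' independently, a spurious patch is gained from background at the rim, so
#' the expected label volume does not drift with severity; (3)
#' near-interface swaps — foreground voxels of other labels inside the shell
#' are captured with a small severity-scaled probability. Because the flip
#' budget scales
#' like a surface, small structures (high surface-to-volume ratio) lose Dice
#' faster than large ones, as real segmentations do; and because it is
#' computed from the volume rather than the realized surface, a rough,
#' already-degraded input suffers the same expected loss as a smooth one.
#'
#' @param gt a [LabelMap-class].
#' @param severity non-negative degradation intensity; 0 returns \code{gt}
#'   unchanged. Either a single number applied to every structure, or one
#'   value per scheme label, so individual structures can fail while others
#'   stay intact (a teres minor lost to fatty infiltration, say, in an
#'   otherwise clean case). At the default rates, severity around 1 costs a
#'   64^3 bone a few percent Dice and the smallest muscle roughly ten
#'   percent.
#' @param seed integer seed.
#' @return A degraded [LabelMap-class] on the same grid.
#' @export
degradeLabelMap <- function(gt, severity, seed = 1) {
  stopifnot(is(gt, "LabelMap"), all(severity >= 0),
            length(severity) %in% c(1L, length(gt@scheme@labelIds)))
  if (all(severity == 0)) return(gt)
  sev <- rep(severity, length.out = length(gt@scheme@labelIds))
  bg <- gt@scheme@backgroundId
  withSeed(seed, {
    v <- gt@voxels
    d <- dim(v)
    for (li in seq_along(gt@scheme@labelIds)) {
      l <- gt@scheme@labelIds[li]
      severity <- sev[li]
      idx <- which(v == l)
      if (!length(idx) || severity == 0) next
      # all morphology happens inside the label's padded bounding box
      ai <- arrayInd(idx, d)
      lo <- pmax(apply(ai, 2, min) - 5L, 1L)
      hi <- pmin(apply(ai, 2, max) + 5L, d)
      xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
      sub <- v[xs, ys, zs, drop = FALSE]
      mask <- sub == l
      # flip budget scales with the surface of an equivalent smooth shape
      # (V^(2/3)), not the realized surface: a rougher input then suffers the
      # same expected Dice loss as a smooth one at equal severity
      budget <- 0.58 * severity * stats::runif(1, 0.85, 1.15) *
        length(idx)^(2 / 3)
      surf <- which(mask & !erode6(mask))
      shell <- which(dilate6(mask) & !mask)
      growable <- shell[sub[shell] == bg]
      # boundary error as coherent dents and bumps: small balls removed
      # around surface seeds and added around shell seeds (speckle-free
      # noise keeps the surface area, and hence the ensemble-overlap
      # geometry, severity-independent)
      nClust <- round(budget / 9)
      if (nClust > 0 && length(surf)) {
        dents <- sample(surf, min(length(surf), nClust))
        for (s in dents) {
          sub <- swapPatch(sub, arrayInd(s, dim(sub))[1, ],
                           stats::runif(1, 1, 2), l, bg)
        }
      }
      if (nClust > 0 && length(growable)) {
        bumps <- sample(growable, min(length(growable), nClust))
        for (s in bumps) {
          sub <- swapPatch(sub, arrayInd(s, dim(sub))[1, ],
                           stats::runif(1, 1, 2), bg, l)
        }
      }
      # near-interface mislabeling: capture other labels touching the shell
      other <- shell[sub[shell] != bg & sub[shell] != l]
      steal <- other[stats::runif(length(other)) < min(0.5, 0.08 * severity)]
      sub[steal] <- l
      # regional patch loss and spurious patch gain, sized as a fraction of
      # the structure volume so the relative Dice impact is comparable
      # across structure sizes; loss and gain are symmetric so the expected
      # label volume stays severity-independent
      patchRadius <- function(fg) {
        frac <- 0.005 + 0.01 * severity * stats::runif(1)
        max(1, (3 * frac * length(fg) / (4 * pi))^(1 / 3))
      }
      if (stats::runif(1) < min(1, 0.15 * severity)) {
        fg <- which(sub == l)
        if (length(fg)) {
          ctr <- arrayInd(fg[sample.int(length(fg), 1)], dim(sub))[1, ]
          sub <- swapPatch(sub, as.integer(ctr), patchRadius(fg), l, bg)
        }
      }
      if (stats::runif(1) < min(1, 0.15 * severity)) {
        fg <- which(sub == l)
        rim <- which(dilate6(sub == l) & sub == bg)
        if (length(fg) && length(rim)) {
          ctr <- arrayInd(rim[sample.int(length(rim), 1)], dim(sub))[1, ]
          sub <- swapPatch(sub, as.integer(ctr), patchRadius(fg), bg, l)
        }
      }
      v[xs, ys, zs] <- sub
    }
    LabelMap(v, spacing = gt@spacing, scheme = gt@scheme)
  })
}

#' Specification of the case-level degradation process
#'
#' \code{caseSeverity} drives the true accuracy of the final prediction (the
#' correction Dice); \code{auxJitter} scales the disagreement among the
#' auxiliary predictions; \code{coupling} links the two. The auxiliary
#' degradation intensity of a case is
#' \deqn{j = auxJitter \cdot (coupling \cdot caseSeverity +
#'       (1 - coupling) \cdot u), \quad u \sim U(0, 3),}
#' so at coupling 1 the ensemble disagrees in exact proportion to how wrong
#' the final prediction is (the informative regime the metrics exploit), and
#' at coupling 0 disagreement is pure noise, independent of accuracy (the
#' negative control).
#'
#' @param caseSeverity non-negative severity of the final prediction; a
#'   scalar, or one value per scheme label for partial-failure cases (see
#'   [degradeLabelMap()]).
#' @param auxJitter non-negative scale of auxiliary disagreement (default 1).
#' @param coupling correlation dial in \[0, 1\] (default 1).
#' @param nAux number of auxiliary predictions (default 5, the usual
#'   cross-validation ensemble size).
#' @param seed integer seed.
#' @return A \code{DegradationSpec} list.
#' @export
degradationSpec <- function(caseSeverity, auxJitter = 1, coupling = 1,
                            nAux = 5, seed = 1) {
  stopifnot(all(caseSeverity >= 0), auxJitter >= 0, coupling >= 0,
            coupling <= 1, nAux >= 2)
  structure(list(caseSeverity = caseSeverity, auxJitter = auxJitter,
                 coupling = coupling, nAux = as.integer(nAux),
                 seed = as.integer(seed)),
            class = "DegradationSpec")
}

#' Simulate one case: ensemble plus corrected segmentation
#'
#' The final prediction is the ground truth degraded at the case severity;
#' each auxiliary is an independent further degradation of the final
#' prediction at the coupled jitter intensity; the corrected segmentation is
#' the ground truth itself (the expert fully restores truth). A
#' partial-correction mode (\code{partialCorrection > 0}) instead returns a
#' mildly re-degraded ground truth, emulating an expert who stops short of
#' voxel perfection.
#'
#' @param gt the ground-truth [LabelMap-class].
#' @param dspec a [degradationSpec()].
#' @param partialCorrection severity of the residual error left by the
#'   expert (default 0 = perfect correction).
#' @return A list with \code{ensemble} (an [EnsembleSet-class]),
#'   \code{corrected} (a [LabelMap-class]) and \code{jitter} (the realized
#'   auxiliary intensity).
#' @export
simulateCase <- function(gt, dspec, partialCorrection = 0) {
  stopifnot(inherits(dspec, "DegradationSpec"))
  final <- degradeLabelMap(gt, dspec$caseSeverity, seed = dspec$seed)
  u <- withSeed(dspec$seed + 1L, stats::runif(1, 0, 3))
  jitter <- dspec$auxJitter *
    (dspec$coupling * dspec$caseSeverity + (1 - dspec$coupling) * u)
  aux <- lapply(seq_len(dspec$nAux), function(k) {
    degradeLabelMap(final, jitter, seed = dspec$seed + 100L + k)
  })
  corrected <- if (partialCorrection > 0) {
    degradeLabelMap(gt, partialCorrection, seed = dspec$seed + 2L)
  } else gt
  list(
    ensemble = EnsembleSet(final, aux,
                           sourceMeta = lapply(seq_len(dspec$nAux),
                                               function(k) list(member = k))),
    corrected = corrected,
    jitter = jitter
  )
}

#' Per-label severity bands of the default phantom
#'
#' The severities at which each default-phantom structure is clearly within
#' (\code{good}) or clearly past (\code{bad}) its goodness threshold, leaving
#' a margin to the severity range where the structure's truth class would be
#' decided by degradation noise rather than by accuracy. The intervals come
#' from measured correction-Dice tails of the default generator (extremes
#' over 200 seeded degradations per candidate edge at 64^3): each
#' structure's \code{good} band ends where the observed minimum still clears
#' its threshold and its \code{bad} band starts where the observed maximum
#' stays clearly below it. Small or flat structures (teres minor, scapula)
#' fail at much lower severities than the compact humerus.
#'
#' @return A list of two matrices (\code{good}, \code{bad}), one severity
#'   interval per label row.
#' @export
defaultSeverityBands <- function() {
  list(
    good = rbind(humerus = c(0, 0.30), scapula = c(0, 0.25),
                 supraspinatus = c(0, 0.70), subscapularis = c(0, 0.80),
                 infraspinatus = c(0, 0.70), teres_minor = c(0, 0.40)),
    bad = rbind(humerus = c(1.2, 3), scapula = c(1.0, 3),
                supraspinatus = c(2.2, 3), subscapularis = c(2.3, 3),
                infraspinatus = c(2.2, 3), teres_minor = c(1.8, 3))
  )
}

#' Severity schedule with per-structure failures
#'
#' Draws one severity profile per case: with probability \code{pAllGood} the
#' case is clean (every structure in its \code{good} band); otherwise a
#' random non-empty subset of structures fails, each drawn from its own
#' \code{bad} band while the rest stay good. This reproduces the failure
#' patterns of real segmentation cohorts — a single muscle lost in an
#' otherwise fine case, artifact cases failing several structures at once,
#' and wholesale failures — and it keeps every structure away from the
#' knife-edge severities at which its truth class would be decided by noise,
#' so the two classes have separable metric distributions per label.
#'
#' @param n number of cases.
#' @param seed integer seed.
#' @param bands per-label severity bands, as from [defaultSeverityBands()].
#' @param pAllGood probability of a fully accurate case.
#' @param pLabelFail per-structure failure probability within a failing case.
#' @return An \code{n} x labels matrix of severities (cases in rows).
#' @export
severitySchedule <- function(n, seed = 1, bands = defaultSeverityBands(),
                             pAllGood = 0.4, pLabelFail = 0.5) {
  stopifnot(n >= 1, identical(rownames(bands$good), rownames(bands$bad)))
  nl <- nrow(bands$good)
  withSeed(seed, {
    out <- t(vapply(seq_len(n), function(i) {
      fail <- rep(FALSE, nl)
      if (stats::runif(1) > pAllGood) {
        fail <- stats::runif(nl) < pLabelFail
        if (!any(fail)) fail[sample.int(nl, 1)] <- TRUE
      }
      lo <- ifelse(fail, bands$bad[, 1], bands$good[, 1])
      hi <- ifelse(fail, bands$bad[, 2], bands$good[, 2])
      stats::runif(nl, lo, hi)
    }, numeric(nl)))
    colnames(out) <- rownames(bands$good)
    out
  })
}

#' Simulate a reproducible cohort of cases
#'
#' One phantom (with per-case anatomical jitter) and one simulated case per
#' severity value. Per-case seeds are derived arithmetically from the master
#' seed, so extending the severity list never perturbs earlier cases. When
#' \code{dir} is given, the volumes are written as NIfTI files together with
#' a \code{manifest.csv} (case_id, role, file, severity) consumable by the
#' command-line calibration workflow.
#'
#' @param spec a [phantomSpec()]; its seed field is overridden per case.
#' @param severities numeric vector of scalar case severities, or a cases x
#'   labels matrix of per-label severities (default: a [severitySchedule()]
#'   with per-structure failures); the cohort spans both
#'   goodness classes when these straddle the degradation level at which
#'   structures cross their correction thresholds.
#' @param auxJitter,coupling,nAux passed to [degradationSpec()].
#' @param seed master seed.
#' @param dir optional output directory for volumes + manifest.
#' @param partialCorrection passed to [simulateCase()].
#' @return Invisibly, a list of cases, each with \code{case_id},
#'   \code{severity}, \code{ensemble}, \code{corrected}.
#' @export
simulateCohort <- function(spec, severities = severitySchedule(20, seed),
                           auxJitter = 1, coupling = 1,
                           nAux = 5, seed = 1, dir = NULL,
                           partialCorrection = 0) {
  stopifnot(inherits(spec, "PhantomSpec"), length(severities) >= 1)
  sevList <- if (is.matrix(severities)) {
    lapply(seq_len(nrow(severities)), function(i) severities[i, ])
  } else {
    as.list(severities)
  }
  cases <- lapply(seq_along(sevList), function(i) {
    caseSeed <- (seed + i * 9973L) %% 2000000011L
    gt <- makePhantom(phantomSpec(spec$gridShape, spec$spacing, spec$scheme,
                                  spec$geometry, spec$jitterVox,
                                  seed = caseSeed))
    sim <- simulateCase(gt, degradationSpec(sevList[[i]], auxJitter,
                                            coupling, nAux,
                                            seed = caseSeed + 1L),
                        partialCorrection = partialCorrection)
    list(case_id = sprintf("case%03d", i), severity = sevList[[i]],
         ensemble = sim$ensemble, corrected = sim$corrected)
  })
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest <- do.call(rbind, lapply(cases, function(cs) {
      cdir <- file.path(dir, cs$case_id)
      dir.create(cdir, showWarnings = FALSE)
      files <- c(final = "final.nii.gz", corrected = "corrected.nii.gz")
      writeLabelMap(finalPrediction(cs$ensemble), file.path(cdir, files["final"]))
      writeLabelMap(cs$corrected, file.path(cdir, files["corrected"]))
      auxRows <- lapply(seq_along(auxiliaries(cs$ensemble)), function(k) {
        f <- sprintf("aux%02d.nii.gz", k)
        writeLabelMap(auxiliaries(cs$ensemble)[[k]], file.path(cdir, f))
        data.frame(case_id = cs$case_id, role = sprintf("aux%02d", k),
                   file = file.path(cs$case_id, f), severity = sevString(cs$severity))
      })
      rbind(
        data.frame(case_id = cs$case_id, role = "final",
                   file = file.path(cs$case_id, files["final"]),
                   severity = sevString(cs$severity)),
        data.frame(case_id = cs$case_id, role = "corrected",
                   file = file.path(cs$case_id, files["corrected"]),
                   severity = sevString(cs$severity)),
        do.call(rbind, auxRows)
      )
    }))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  invisible(cases)
}

#' Metric panels and correction records of a simulated cohort
#'
#' Convenience accessors running [computeMetricPanel()] and
#' [extentOfCorrection()] over every case of a [simulateCohort()] result.
#'
#' @param cohort a list of cases from [simulateCohort()].
#' @return A combined data.frame over all cases.
#' @export
cohortMetricPanel <- function(cohort) {
  do.call(rbind, lapply(cohort, function(cs) {
    computeMetricPanel(cs$ensemble, caseId = cs$case_id)
  }))
}

#' @rdname cohortMetricPanel
#' @export
cohortCorrectionRecords <- function(cohort) {
  do.call(rbind, lapply(cohort, function(cs) {
    extentOfCorrection(finalPrediction(cs$ensemble), cs$corrected,
                       caseId = cs$case_id)
  }))
}
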