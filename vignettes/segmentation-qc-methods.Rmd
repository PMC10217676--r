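---
title: "Methods: label-wise segmentation QC from ensemble disagreement"
author: "SegEnsembleQC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label-wise segmentation QC from ensemble disagreement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(SegEnsembleQC)
```

## The model

SegEnsembleQC predicts, per structure and per case, whether a multi-label 3D
segmentation is accurate enough to use without manual correction. The
underlying assumption is epistemic: where an ensemble of segmentation models
(cross-validation subnetworks, stochastic forward passes) disagrees, the
combined final prediction is likely to be wrong. The package quantifies this
disagreement per label with seven metrics on hard label maps — the
intersection-over-union and intersection-over-prediction of the auxiliary
masks, their Dice-scale transforms $x \mapsto 2x/(1+x)$, the mean and median
Dice between each auxiliary and the final prediction, and the coefficient of
variation of the auxiliary label volumes. All of them are voxel-set
operations on one shared grid; spacing and orientation metadata play no role
beyond I/O, and label volumes enter only through the scale-free CV, so voxel
counts are used rather than mm³.

Accuracy itself is defined operationally, as the **extent of correction**:
the Dice coefficient between the raw prediction and the expert-corrected
segmentation of the same case. This matches how such systems are actually
used — a prediction that the expert accepts untouched scores exactly 1.0, no
matter how it compares to an independent re-segmentation. The consequence is
a point mass at 1.0 and a generally non-uniform distribution, which depresses
coefficients of determination relative to studies that regress against
independent ground truth; R² values must be read with that in mind.

A label is **insufficiently accurate** when its correction Dice is strictly
below a structure-class threshold: 0.975 for bones, 0.925 for muscles by
default (`goodnessRule()`). Bones are held to the stricter standard because
downstream bone morphometry depends on surface landmarks, while muscle
measures (volume, fat fraction) integrate over the whole structure. A value
exactly at the threshold is sufficient; the same boundary convention applies
to the metric thresholds at classification time (flag only when strictly
worse).

## Degenerate panels

Disagreement metrics have well-defined degeneracies and the panel reports
them explicitly instead of zeroing them: a label absent from every volume
gives an all-`NA` row flagged `all_empty`; an empty auxiliary intersection
with an empty union gives IoU 1 with `aux_all_empty` set (all members agree
the label is absent — downstream code can distrust this agreement); an empty
final mask makes IoP undefined (`final_empty`); and because the auxiliary
intersection need not be a subset of the final mask, IoP can exceed 1 and is
reported unclamped with `iop_over_one` set. At classification time every
undefined metric value is flagged insufficient fail-safe: a structure whose
existence the ensemble cannot even agree on must go to a human. The CV uses
the sample (n−1) standard deviation by default, switchable to the population
form; with the usual N = 5 auxiliaries the difference is ~12 % of the value
and irrelevant to ranking.

## Threshold calibration

Label-specific thresholds on the chosen metric are calibrated by maximizing
a sensitivity-weighted Youden objective
$$J_w = w \cdot Se + Sp, \qquad w = 2 \text{ by default},$$
with *insufficient* as the positive class, so sensitivity is the detection
rate of bad segmentations and the weight encodes that a missed failure costs
more than a false alarm ($w = 1$ reduces to the classical Youden index up to
a constant). The exact weighted form is a package choice; the weight is an
exposed parameter. Candidate thresholds are the midpoints between adjacent
distinct observed values plus $\pm\infty$ sentinels — a finite set that an
exhaustive scan can verify, with no grid-resolution parameter. Ties in $J_w$
break toward higher sensitivity, then toward the threshold that flags more
aggressively. The calibrated operating point is invariant under strictly
monotone relabeling of the metric, and the tests check the whole procedure
against a brute-force scan on every small input.

Metric selection uses the coefficient of determination between metric and
correction Dice, implemented as the squared Pearson correlation (identical
to the regression R² in the simple linear case, so the two readings of
"coefficient of determination between two variables" coincide). R² is
computed both pooled over all (case, label) instances and per label;
constant metrics are reported `NA` and rank last. Dice-family metrics are
`higher_is_better`; CV is `lower_is_better`; orientation is stored per
metric in the calibration table.

## The synthetic cohort generator

The generator stands in for a clinical cohort with a trained ensemble, which
no desk-scale package can ship. It emulates exactly the features the QC
method exploits and nothing more.

**Phantom.** Six non-overlapping structures on a 64³ grid (1 mm spacing by
default): two compact ellipsoid "bones" and four elongated capsule
"muscles", with the size ordering of the shoulder — bones (≈6000 and ≈3900
voxels) larger than muscles, teres minor smallest (≈600 voxels). Geometry is
specified in grid-normalized coordinates; per-case seeded jitter (±2 voxels)
emulates anatomical variability. Rasterization is deterministic given the
seed, and later structures never overwrite earlier ones.

**Degradation.** `degradeLabelMap()` applies three seeded morphological
operators per label, chosen to map onto the observed failure modes of real
segmentation networks: coherent boundary noise (a flip budget of
0.58·severity·u·V^(2/3) voxels, u ~ U(0.85, 1.15), spent carving small dents
around random surface seeds and adding small bumps around random shell seeds
— boundary error), symmetric patch noise (with probability 0.15·severity
each, a surface patch sized as a fraction (0.005 + 0.01·severity·u) of the
structure's volume is lost to background, and a spurious patch is gained at
the rim — regional loss and artifact-driven false positives), and capture of
neighbouring labels inside the one-voxel shell (interface mislabeling).
Severity 0 is the identity and expected Dice decreases strictly with
severity. Three choices are deliberate, all serving the same goal — the
perturbation a volume suffers must depend on the commanded severity, not on
the volume's own history. The flip budget scales like the surface of an
equivalent *smooth* shape (V^(2/3)), so small structures lose Dice faster
than large ones, as real predictions do, but a rough, already-degraded input
suffers the same expected loss as a smooth one (a budget tied to the
realized surface would leak the final prediction's severity into every
disagreement metric of the uncoupled negative control). Boundary noise is
clustered into dents and bumps rather than independent voxel speckle,
because speckle balloons the surface area with severity and thereby dilutes
the overlap geometry that the N-way intersection metrics measure. And patch
loss is balanced by patch gain so the expected label volume — the
denominator of the intersection-over-prediction metric — does not drift with
severity.

**Cases and coupling.** A case is built as final = degrade(gt, severity);
auxiliaries = nAux independent degradations *of the final* at intensity
$j = \text{auxJitter}\,(c \cdot \text{severity} + (1-c)\,u)$, $u \sim
U(0,3)$; corrected = gt (the expert fully restores truth; a
partial-correction mode re-degrades gt mildly instead). At coupling $c = 1$
the ensemble's disagreement is a deterministic function of how wrong the
final prediction is — the informative regime the metrics rely on; at $c = 0$
disagreement is noise independent of accuracy, a negative control in which
every metric's R² should collapse.

**Severity schedule.** Per-structure severities come from measured bands.
The tail of each structure's correction Dice was measured at candidate band
edges (200 seeded degradations per edge, 64³); a structure's `good` band
ends at the severity where the observed minimum still clears its goodness
threshold with a margin, and its `bad` band starts where the observed
maximum stays clearly below it (`defaultSeverityBands()`). The smallest
structure has the widest Dice tails — a single unlucky dent is a visible
fraction of the teres minor — so its bands are the most conservative. Because the six
crossing regions tile the severity axis almost completely, no single global
severity can make some structures fail while keeping the rest safely good —
so `severitySchedule()` draws *per-label* profiles: a case is clean with
probability 0.4, otherwise a random non-empty subset of structures fails,
each within its own bad band. This reproduces the clinically observed
failure patterns (a single atrophic muscle lost in an otherwise clean case,
artifact cases failing several structures, wholesale failures) and keeps
every structure away from the knife-edge severities at which its truth class
is decided by degradation noise rather than accuracy — the separability that
any threshold-based detector, and the parameter-recovery tests, presuppose.

**What passing tests do and do not show.** The synthetic cohorts demonstrate
that the pipeline recovers an operating point with full sensitivity whenever
ensemble disagreement genuinely tracks accuracy and the two truth classes
are separable per label, and that it finds nothing when disagreement is
uninformative. They do not show that real ensembles satisfy these premises:
real auxiliary predictions share training data (correlated errors can
produce confident agreement on a wrong boundary), real corrections are
partial and rater-dependent, and real anatomies have contact interfaces and
topology the phantom lacks. Borderline cases — structures whose true
accuracy sits exactly at the goodness threshold — are intrinsically
undecidable by any metric and are excluded from the generator by design, so
the synthetic sensitivity of 1 should be read as "no clear failure slips
through", not as a clinical guarantee.

## Numerical and design choices

* Empty-vs-empty Dice is 1 (perfect agreement on absence), empty vs
  non-empty is 0.
* Sizes used in the shipped analyses: calibration cohorts of 50 cases and
  held-out cohorts of 24 cases at 64³ with 5 auxiliaries — large enough for
  ≈300 calibration instances (both classes per label with overwhelming
  probability) while keeping a full pipeline run in minutes on one CPU. The
  oracle-agreement property tests run 1000 random ensembles on grids up to
  6³, where brute-force voxel enumeration is exact and fast.
* Random streams are split arithmetically per case and per auxiliary from
  one master seed, so extending a cohort never perturbs existing cases, and
  every operation is a pure function of (inputs, seed).
* Grid compatibility within an ensemble is enforced, never repaired: a
  shape/spacing/scheme mismatch is an error, not a silent resample.
* The command-line layer writes all outputs atomically (temp-then-rename)
  and distinguishes usage errors (exit 2) from data/validation errors
  (exit 3).
* NIfTI I/O uses RNifti; NRRD support is a minimal built-in codec (3D
  integer volumes, raw or gzip encoding, spacing via `spacings:`/`space
  directions:`), sufficient for label maps; detached headers and non-integer
  types are out of scope.

## Known limitations

Only hard label maps are consumed: softmax-probability uncertainty
(entropy, variance) and voxel-wise or regional uncertainty maps are out of
scope, as are DICOM ingestion, resampling/registration and any intensity
processing. The correction-extent truth inherits the biases of the
correcting expert. Thresholds calibrated on one anatomy, protocol or model
family do not transfer; recalibration on a cohort from the target
distribution is expected. The shipped shoulder preset is a reference
calibration for the default six-structure scheme, not a universal default.
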