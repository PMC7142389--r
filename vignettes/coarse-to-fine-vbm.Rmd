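---
title: "Coarse-to-fine feature selection for tissue-map classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-to-fine feature selection for tissue-map classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vbmrfe)
```

## The problem

Voxel-based morphometry (VBM) turns each subject's structural MRI into
smoothed, modulated tissue maps — per-voxel gray-matter (GM) or white-matter
(WM) volume on a common grid. A two-group study (patients vs. controls)
then faces a severe `p >> n` problem: on the order of 10^5 informative
voxels against fewer than 10^2 subjects. Mass-univariate tests find
group-level differences but do not classify individuals; a classifier on
all voxels overfits. The pipeline implemented here takes the middle road,
a *coarse-to-fine* feature selection:

1. **Coarse screen** — a voxelwise pooled two-sample *t*-test,

   $$T = \frac{\bar x_1 - \bar x_2}
   {\sqrt{\dfrac{(N_1-1)S_1^2 + (N_2-1)S_2^2}{N_1+N_2-2}
   \left(\dfrac{1}{N_1}+\dfrac{1}{N_2}\right)}},$$

   thresholded at a two-sided p-value and followed by a cluster-extent
   filter: supra-threshold voxels are grouped into 3D connected components
   and components smaller than `min_cluster` voxels are discarded. The
   larger $|T|$, the more discriminative the voxel.

2. **Fine selection** — recursive feature elimination (RFE) driven by a
   linear soft-margin SVM. The SVM primal
   $\min_{\omega,b,\zeta} \tfrac12\|\omega\|^2 + C\sum_i\zeta_i$ subject to
   $y_i(\omega^\top x_i + b) \ge 1-\zeta_i$, $\zeta_i \ge 0$, is solved in
   its dual; the feature weights are recovered from the dual coefficients
   as $\omega = \sum_i \alpha_i y_i x_i$. Features are ranked by
   $\omega_i^2$ and the lowest-ranked fraction is removed; the fit-rank-
   remove loop repeats until a target fraction of features remains.
   (Slack is the standard hinge $\zeta_i = \max(0,\,1-y_i(\omega^\top x_i + b))$.)

3. **Classifier** — a linear soft-margin SVM on the retained voxels,
   evaluated by leave-one-out (LOO) cross-validation.

The retained voxels are finally grouped into clusters and reported with
sizes, peak coordinates (mm, via the NIfTI affine) and atlas labels — the
biomarker table of a VBM classification study.

## Evaluation metrics

With $N$ positives ($N_1$ correct) and $M$ negatives ($M_1$ correct) the
confusion entries are *per-class proportions*: $TP = N_1/N$, $FN = 1-TP$,
$TN = M_1/M$, $FP = 1-TN$. On these entries,

$$\mathrm{ACC} = \frac{TP+TN}{TP+FN+TN+FP},\quad
\mathrm{SN} = \frac{TP}{TP+FN},\quad
\mathrm{SP} = \frac{TN}{TN+FP},$$
$$\mathrm{GM} = \sqrt{\frac{TP\cdot TN}{(TP+FN)(TN+FP)}},\quad
\mathrm{DM} = \frac{2}{\frac{TP+FN}{TP}+\frac{TP+FP}{TP}},\quad
\mathrm{F2M} = \frac{5}{\frac{4(TP+FN)}{TP}+\frac{TP+FP}{TP}},$$

with $DM = F2M = 0$ at $TP = 0$ by continuity. Because $TP+FN = TN+FP = 1$,
the identities $SN = TP$, $SP = TN$, $ACC = (SN+SP)/2$ and
$GM = \sqrt{SN \cdot SP}$ hold exactly, and the test suite asserts them on
every computed metric set. The AUC is the Mann–Whitney probability (ties
counted 1/2) of the pooled LOO decision scores.

A caution for readers comparing against published per-tissue tables of
these metrics: printed ACC/DM/F2M cells are not always algebraically
consistent with the printed SN/SP under the formulas above (the averaging
protocol behind such cells is typically unstated), whereas the GM cells
are. This package therefore anchors its published-value checks on the GM
identity only.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | two-sided p threshold of the screen (unitless) |
| `min_cluster` | 50 | minimum surviving cluster extent, voxels |
| `connectivity` | 26 | 3D neighbourhood (6 faces / 18 +edges / 26 +corners) |
| `C` | 1.0 | SVM soft-margin penalty |
| `elim_fraction` | 0.05 | fraction of *remaining* features removed per RFE round |
| `retain_fraction` | 0.40 | fraction of screened features kept at stop (≈0.40 for GM, ≈0.14 for WM in tissue-map studies) |
| `fwhm_mm` | 6 | Gaussian smoothing kernel FWHM, mm; σ = FWHM/(2√(2 ln 2)) |

`alpha = 0.05` with extent 50 is the common uncorrected-VBM screening
convention; stricter values shrink the surviving set monotonically (a
property the suite tests). `retain_fraction` is exposed as a free
parameter: the values above gave the best performance in prior tissue-map
work but no optimality is asserted. An optional Bonferroni flag exists for
users who want a corrected screen; the default pipeline is faithful to the
uncorrected-plus-extent convention.

## Design choices where the procedure was open

* **Sidedness.** The screen uses two-sided p-values: group differences in
  tissue volume occur in both directions and the screen should be
  symmetric.
* **Elimination base.** "5% per round" is interpreted against the
  *current* (shrinking) feature set, matching the loop structure of RFE,
  with ⌈·⌉ and a minimum of one feature per round; the final batch is
  truncated so the retained set lands exactly on
  `ceiling(retain_fraction * n)`.
* **Ties.** Equal squared weights are broken by ascending column index;
  cluster peaks (max |T|) by lowest linear voxel index; atlas majority
  labels by smallest label value. All outputs are thereby deterministic.
* **Scaling.** No feature standardization is applied before the SVM —
  smoothed tissue maps are already on a common scale. Note the
  equivariance law: scaling the data by $c>0$ leaves the elimination order
  unchanged when $C$ is rescaled by $1/c^2$ (tested).
* **Nested vs. pooled LOO.** Whether the *t*-screen and RFE are refit
  inside each LOO fold is a protocol choice older studies often leave
  unstated. `loo_evaluate()` implements both: `nested` (default,
  leakage-free — the suite asserts that a fold's selection is invariant to
  the held-out subject's values) and `pooled` (selection once on all
  subjects, SVM refit per fold; optimistic). The mode is recorded in every
  output.
* **Fold failures.** A training fold whose screen survives nowhere
  predicts the training majority class with score 0 and is flagged; this
  keeps the LOO totals well-defined. Note that under LOO with balanced
  groups the training majority is systematically the *other* class, so an
  all-failure evaluation is pessimistic, not chance-level — evaluations of
  null data should relax the screen enough that folds actually fit (see
  below).
* **Degenerate voxels.** Zero pooled variance gives $T=0, p=1$ when the
  group means agree (excluded from survival) and $T=\pm\infty, p=0$
  otherwise; both are flagged.
* **Connectivity default 26**, the most inclusive neighbourhood; 6 and 18
  are available and recorded in output metadata.
* **Coordinates.** Arrays are 1-based as usual in R; world (MNI-style)
  coordinates are obtained by applying the NIfTI affine to 0-based
  indices, so reports and rankings print millimetre coordinates.
* **Smoothing boundaries** are handled by reflection, with the kernel
  truncated at 4σ and renormalised; a compactly supported impulse keeps
  unit mass (tested to 1e-8) and the separable implementation matches
  direct convolution to 1e-10.

## The synthetic cohort generator

No public tissue maps ship with the package; every stage is instead
validated on seeded synthetic cohorts with known ground truth
(`generate_cohort()`). The generator emulates smoothed modulated tissue
maps with localized group differences, as simply as possible so that
ground truth stays exact:

* per-subject volume = `baseline` + a global subject offset
  ~ N(0, `subject_sd`²) + i.i.d. voxel noise ~ N(0, `voxel_sd`²);
* spherical *blobs* add a signed `effect` to group-1 subjects before
  smoothing, so planted regions acquire the smooth boundaries real VBM
  effects have;
* every volume is smoothed at `fwhm_mm` (default 6 mm at 1 mm voxels).

Defaults mirror the scale of a typical two-group structural-MRI study —
34 + 34 subjects, 6 mm FWHM — on a 32³ grid, the size at which a full
nested-LOO run completes in a couple of minutes on one core. The intensity
scale of modulated tissue maps is study-dependent, so `baseline` is
unit-free (default 0.5 with noise s.d. well below it). `subject_sd`
defaults to 0.01, small relative to the *smoothed* voxel noise: a global
offset is spatially constant, and if it dominated the voxel-level variance
the null *t*-field would be perfectly correlated across the volume,
defeating cluster-extent filtering in a way real tissue maps (whose
subject effects vary spatially) do not.

What the generator does *not* emulate: anatomy (no brain-shaped mask or
tissue classes), spatially varying covariance, registration error, scanner
or site effects, covariates such as age and sex, and non-spherical effect
shapes. Passing the recovery tests therefore shows the pipeline recovers
planted smooth localized effects at study scale — not that any particular
accuracy will transfer to real cohorts.

A synthetic atlas (`make_synthetic_atlas()`) partitions the grid into
contiguous boxes by recursive bisection (a seed permutes the label
values), standing in for anatomical atlases in region-report tests.

## Numerical and testing notes

* The SVM solver is LIBSVM (via \pkg{e1071}); the wrapper normalises the
  decision-value orientation so positive scores always mean class +1, and
  the KKT identity $\omega = \sum_i \alpha_i y_i x_i$ is asserted on every
  fit (tolerance 1e-6). An independent solver (\pkg{kernlab}) serves as a
  cross-check in the suite, with agreement at solver tolerance (1e-2).
* Every nontrivial statistic has a brute-force oracle in the test suite:
  pooled *t* vs `stats::t.test(var.equal = TRUE)` (1e-10, 1000 draws),
  connected components vs a naive flood fill (50 random 8³ masks, all
  connectivities), batch RFE vs one-at-a-time elimination (identical
  orders), AUC vs exhaustive pair counting (100 random score sets,
  with ties), smoothing vs direct convolution.
* Null calibration uses unsmoothed cohorts (independent voxels), where the
  rejection rate at `alpha = 0.05` must sit within binomial error of 0.05
  and nested-LOO accuracy within sampling error of 0.5. Null LOO runs use
  a relaxed screen (`alpha = 0.2`, `min_cluster = 2`) so folds exercise
  the classifier rather than the fold-failure path.
* Problem sizes in the shipped tests are the package's chosen desk scale:
  study-scale cohorts (34 + 34) run on 32³ for single runs and 16³ for
  100-seed replication loops; null LOO uses 17 + 17 on 8³ over 12 seeds.
* Determinism: all generator randomness flows from the spec seed (the
  caller's RNG state is restored), LIBSVM is deterministic for fixed
  input, and tie-breaks are explicit — rerunning a pipeline with the same
  config and seed reproduces `summary.json` byte for byte (tested).

## Known limitations

* Screening offers no permutation-based cluster inference and no
  covariate adjustment; the extent filter controls nothing formally — it
  is a feature-selection heuristic, as in the uncorrected-VBM tradition.
* Only linear kernels, binary labels and a single tissue map per subject;
  no multimodal fusion, no resampling between grids, no 4D data.
* LOO is high-variance; with 68 subjects the metrics move in steps of
  1/34 per class. The harness is written so alternative selectors could be
  plugged in ahead of the SVM, but ships only the t-screen, RFE and their
  composition.
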