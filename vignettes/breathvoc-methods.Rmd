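---
title: "Breath VOC biomarker discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath VOC biomarker discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathvoc)
library(dplyr)
```

## The problem

Exhaled breath carries hundreds of volatile organic compounds (VOCs), and
portable gas chromatography (GC) can resolve roughly ninety of them in a
ten-minute separation of a single breath sample. Panels of a few such peaks
can distinguish asthmatic from non-asthmatic adults, separate atopic
(allergically sensitized) non-asthmatic controls from both, and stratify
asthmatics by clinically meaningful variables — inhaled corticosteroid (ICS)
use, obesity (BMI ≥ 30 kg/m²), blood eosinophil level (≥ 0.3 × 10⁹/L), and
acute upper respiratory illness (URI). breathvoc implements that entire
analysis as a reusable, testable pipeline: a chromatogram simulator with
planted ground truth, a preprocessing chain that turns raw detector traces
into an aligned samples × peaks area matrix, a discriminant-analysis panel
search, and a two-step hierarchical phenotype classifier with PCA score-plot
visualization.

Because clinical breath cohorts are rarely public, the simulator is a
first-class component: every downstream claim the package makes is checked
against data whose truth is known by construction.

## The simulator

A chromatogram is modelled as

$$ y(t) \;=\; \sum_j A_j\, \phi\!\left(t;\, \mu_j + \delta,\ \sigma_j\right)
\;+\; b(t) \;+\; \varepsilon(t), $$

where $\phi$ is a unit-area Gaussian (an exponentially modified Gaussian with
tailing constant $\tau$ is available and off by default, since peak shape is
otherwise unidentified), $\delta \sim N(0, s_{rt}^2)$ is a *rigid* per-sample
retention-time shift — the dominant misalignment mode of a short
isothermal-ramp column — $b(t)$ is a slow drift (intercept, linear term, and
a sinusoid), and $\varepsilon$ is white detector noise.

Peak areas vary across samples as lognormals, $A_j = \bar A_j \cdot e_j(g)
\cdot L$, with $L$ lognormal with unit mean and coefficient of variation
`area_cv`, so areas stay positive and the mean area ratio between groups
equals the planted multiplicative effect $e_j(g)$ exactly. Only designated
marker peaks carry group effects; the rest form a shared background, because
most breath peaks come from diet, environment and general metabolism rather
than disease.

Defaults emulate the study conditions throughout: 600 s separations sampled
at 4 Hz, ~90 library peaks on a jittered grid over 30–570 s with widths
σ ∈ [0.8, 1.2] s (grid spacing keeps neighbours ≥ 4σ apart, i.e. resolvable),
apex heights log-uniform over 30–600 detector units, `area_cv` 0.2,
retention jitter SD 0.5 s, and unit noise SD. Where a real value was never
stated (heights, widths, drift amplitudes) the defaults are what a
practitioner would call a realistic portable-GC breath run, chosen once.

What the simulator does *not* emulate — co-eluting compounds under a single
peak, detector response nonlinearity, Tedlar-bag off-gassing, within-subject
day-to-day drift — bounds what passing tests show about real data: they
validate the algorithms under the stated statistical model, not instrument
physics.

## Preprocessing

The chain is baseline correction → smoothing → peak detection and
integration → total-area normalization → retention-time alignment
(`process_chromatograms()` runs all five).

**Baseline.** An asymmetric penalized least-squares smoother: minimize
$\sum_i w_i (y_i - z_i)^2 + \lambda \lVert D^2 z \rVert^2$ with $w_i = p$
above the current fit and $1-p$ below, iterated to convergence. Two details
matter and were calibrated once against planted-truth simulations. First, on
pure noise the asymmetric weights settle the fit $u(p)\,\sigma$ *below* the
true baseline, where $u$ solves the Gaussian balance equation
$p\,E[(y-z)_+] = (1-p)\,E[(z-y)_+]$; the package computes $u(p)$ and adds the
offset back (with $\sigma$ estimated from the high-frequency smoothing
residual), so peak-free regions come out zero-mean. Second, stiffness: a
baseline soft enough to follow the 9-second valleys of a dense trace eats
2–5 % of every small peak's area. The defaults ($\lambda = 3\times10^7$,
$p = 10^{-4}$ at 4 Hz) keep the baseline too stiff to enter valleys while
still tracking drift on the tens-of-seconds scale; planted-area error drops
below 1 %. A rolling-minimum fallback exists for non-smooth baselines.

**Smoothing.** Savitzky–Golay, window 9 samples, order 3 — preserves apex
positions and areas of peaks sampled at ≥ 3 points per σ far better than a
moving average. A window below `polyorder + 2` interpolates exactly and is
rejected.

**Noise estimation.** The detection threshold needs the raw white-noise SD.
On peak-dense breath traces almost no baseline is peak-free, so the usual
MAD-of-first-difference estimate is inflated several-fold; the pipeline
instead uses the MAD of the Savitzky–Golay residual (raw − smoothed),
rescaled by the residual operator's variance $1 - 2c_0 + \sum c^2$ — peaks
are smooth on the filter's scale and drop out. Both estimators are exposed
in `estimate_noise()`.

**Detection and integration.** Local maxima above
`snr_min` (default 5) × noise SD, at least `min_separation` (2 s) apart
(taller apex wins). Bounds extend to the flanking valley or to 0.5 % of apex
height; the integral is a trapezoid minus the valley-to-valley chord, which
removes the locally linear contribution of neighbouring tails. Two guards
reflect ordinary integrator practice and reject residual-drift artifacts:
peaks broader than `max_fwhm` (10 s — real peaks here are 2–3 s wide) and
peaks below an area-reject threshold (`min_area_frac`, 10⁻³ of the largest
peak) are dropped.

**Normalization.** Areas are divided by their per-chromatogram total. The
dominant nuisance in bag-sampled breath is exhaled-volume/sampling
variability, which total-area normalization cancels; it does mean each value
is a *relative* abundance.

**Alignment.** Apex times of all samples are pooled and clustered by single
linkage: a gap above `rt_tolerance` (2 s) opens a new consensus peak, and
clusters are recursively split at their largest internal gap while their span
exceeds `2 × rt_tolerance` or while any sample contributes two peaks (the
peak nearer the cluster median stays). Consensus peaks are numbered by
ascending median retention time — the integer "peak ID" namespace that panels
refer to. The numbering is cohort-relative: on synthetic data it reproduces
the *kind* of namespace the study prints (IDs like 7, 32, 50), not the same
integers. Missing peaks are zero-filled, never imputed — a peak below
detection genuinely contributes ~0 area. No warping is used, matching the
rigid-shift error model; permuting sample order cannot change the result
because pooled peaks are sorted before clustering.

## Panel selection

For a two-class comparison the package fits a regularized linear
discriminant on z-scored normalized areas: pooled within-class covariance
shrunk toward its diagonal, $S_\gamma = (1-\gamma) S + \gamma\,
\mathrm{diag}(S)$ with $\gamma = 0.1$, because candidate subsets are drawn
from ~100 peaks at n ≈ 45 samples. The decision value is $w^\top z + b$ with
$w = S_\gamma^{-1} (\mu_1 - \mu_0)$ and the threshold at the midpoint of the
projected class means (equal priors). Standardization never changes the
fitted classifications — only the scale on which margins are measured.

`select_subset()` searches subsets of size ≤ `k_max`, scoring each by
**leave-one-out accuracy** first. LOO is the deterministic, lowest-variance
choice at these sample sizes; no random folds exist anywhere in the package.
Ties are broken by the **cross-validated margin**: the mean over LOO folds
of the held-out sample's signed distance to that fold's decision boundary.
This choice was made after the obvious alternatives measurably failed the
package's own planted-marker recovery property. A *training-set* margin
(minimum or mean) grows fastest by memorizing noise dimensions once accuracy
saturates, so greedy search fills panels with background peaks; a *held-out
minimum* is owned by the single hardest sample, which a genuinely
informative but redundant marker need not help. The held-out mean tracks
class separation: in traces of the recovery experiment it admits all three
planted markers in the first three steps. The training-set minimum margin —
the natural "distance from the data to the boundary", positive exactly when
the training set is perfectly separated — is still computed for every panel
and reported as `boundary_distance`.

Search is exhaustive (all subsets) for ≤ 20 candidate peaks with
`k_max ≤ 4`, otherwise greedy forward selection under the same ordering,
stopping when no single addition improves (accuracy, CV margin). Remaining
ties prefer smaller panels, then lexicographically smaller peak-id sets, so
repeated runs return the identical panel. The LOO accuracy of a panel chosen
by maximizing LOO accuracy is optimistically biased — the known wrapper
caveat; no nested cross-validation is attempted in this version.

## Two-step phenotype classification

Atopy confounds a single asthma/non-asthma split: atopic non-asthmatic
subjects sit between the other two groups on asthma markers. The classifier
therefore routes hierarchically (`fit_hierarchical()`,
`classify_two_step()`):

1. **Step 1** — a panel trained on asthma vs non-asthma/non-atopic assigns
   each sample a side (atopic controls are excluded from this training set).
2. **Step 2a** — asthma-side samples are re-tested with an asthma vs
   atopic panel and may be relabelled `non-asthma/atopic`.
3. **Step 2b** — control-side samples are re-tested with an atopic vs
   non-atopic panel likewise.

Exactly one of the three labels results; the three-class output comes from
routing, never from a direct three-class model. Samples near the step-1
boundary are routed strictly by its sign — the step order is fixed and no
uncertainty band is modelled. Step-2 training strata can be subsampled to a
fixed size per group (`n_per_group`, seeded), mirroring designs where the
scarce atopic group is paired with equal random draws of the others; by
default every available sample is used. On simulated three-group cohorts
with the atopic profile intermediate on step-1 markers, step 1 alone
misroutes every atopic sample by construction, and the two-step rule's
held-out three-class accuracy exceeds the step-1-only rule's — the package's
property test and acceptance script both recompute this.

Subgroup panels (`subgroup_panels()`) run the same selection inside the
asthma stratum for ICS / obesity / eosinophil / URI dichotomies. The
dichotomies are *rederived* from raw BMI and eosinophil values at the
clinical thresholds (≥ 30 kg/m², ≥ 0.3 × 10⁹/L); flags supplied in the
metadata are ignored, so an inconsistent input cannot leak through.
`longitudinal_trajectory()` orders a subject's repeated visits in an
existing PCA plane and flags boundary crossings between consecutive visits
(the baseline → illness trajectories of the URI comparison).

## PCA visualization

`pca_project()` standardizes the panel columns, runs PCA, and fixes each
loading's sign so its largest-magnitude element is positive (making scores
deterministic). The LDA hyperplane is re-expressed in the PC1–PC2 plane as
the straight line $a_1\,\mathrm{PC1} + a_2\,\mathrm{PC2} + b = 0$ with
$a = V_{1:2}^\top \tilde w$ — the image of the full hyperplane restricted to
the plane. When the first two components carry most of the variance this
line separates (almost) the same samples as the full-space rule;
`autoplot()` draws it over the score scatter in the yellow of the field's
figures.

## Numerical and degenerate-input policy

Invalid arguments raise classed errors (`breathvoc_invalid`); an unfitted
rule raises `breathvoc_state`. An empty peak table is a *valid* detection
result, but normalization and alignment of nothing is an error. Zero-variance
features pass through standardization unscaled; a tiny ridge
(10⁻¹⁰ × mean diagonal) keeps shrunk covariances invertible; degenerate LOO
folds (a class emptied by the held-out sample) count as misclassified. Time
grids are seconds from injection, uniform; intervals are half-open
`[left, right)`.

## Problem sizes used in checks

The shipped tests and the acceptance script run: enumeration-equivalence on
16-sample, 10-peak matrices; 50 simulated 40-sample cohorts (43 peaks, three
2-fold markers, CV 0.2, weakest peak at SNR 20) through the full
simulate → preprocess → select pipeline; 200 permutation-null replicates of
the search on pure noise (n = 40, 10 peaks); and one train/test pair of
45-sample three-group cohorts for the routing comparison. These sizes give
stable pass/fail behaviour on a single desktop core; nothing in the
methodology depends on them.

## Known limitations

- Co-eluted VOCs under one consensus peak are not deconvolved.
- Alignment assumes rigid shifts; no time warping.
- Reported panel accuracies are selection-biased (no nested CV).
- The simulator's retention times are arbitrary placements, not the real
  compounds' retention times, which are not public.
- Total-area normalization makes areas compositional; effects planted on
  many large peaks at once would distort background shares.
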