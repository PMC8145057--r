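# breathvoc

Discovery and validation of volatile organic compound (VOC) biomarker panels
in exhaled breath analysed by portable gas chromatography (GC), for asthma
diagnosis and phenotyping.

A ten-minute portable-GC separation of one breath sample resolves roughly 90
VOC peaks. Small subsets of those peaks can distinguish asthmatic from
non-asthmatic adults, separate atopic (allergically sensitized) non-asthmatic
controls from both, and stratify asthmatics by inhaled-corticosteroid use,
obesity (BMI ≥ 30 kg/m²), blood eosinophils (≥ 0.3 × 10⁹/L) and acute upper
respiratory illness. breathvoc implements that analysis end to end:

- **simulate** — synthetic breath chromatograms with planted ground truth:
  Gaussian peaks on a 600 s / 4 Hz grid, lognormal area variation,
  multiplicative group effects on designated marker peaks, baseline drift,
  rigid retention-time jitter, detector noise
  (`peak_library()`, `simulate_cohort()`).
- **preprocess** — asymmetric-least-squares baseline correction,
  Savitzky–Golay smoothing, SNR-thresholded peak detection with
  valley-to-valley integration, total-area normalization, and single-linkage
  retention-time alignment into a samples × peaks matrix with integer peak
  ids (`process_chromatograms()` or the individual verbs).
- **select** — biomarker panel search scored by leave-one-out accuracy of a
  regularized two-class linear discriminant (pooled covariance shrunk toward
  its diagonal), ties broken by the cross-validated margin; exhaustive
  enumeration for small problems, greedy forward selection otherwise
  (`select_subset()`, `cv_accuracy()`, `boundary_distance()`).
- **classify** — the two-step hierarchical rule (asthma vs non-atopic
  controls first, then atopy re-tested on each side), subgroup panels within
  the asthma stratum, PCA score plots with the discriminant boundary mapped
  into the PC1–PC2 plane, and longitudinal trajectories
  (`fit_hierarchical()`, `classify_two_step()`, `subgroup_panels()`,
  `pca_project()`, `longitudinal_trajectory()`).

The core statistic: for a candidate peak subset *S*, an LDA with shrunk
pooled covariance Σ̂ = (1−γ)S + γ diag(S), γ = 0.1, gives the decision value
w᷆ᵀz + b, w = Σ̂⁻¹(μ₁−μ₀). Panels maximize leave-one-out accuracy; among
equally accurate panels the one with the largest mean held-out margin wins,
and the training-set minimum margin (`boundary_distance`) is reported with
every panel. All results are deterministic given a seed; fold assignment is
leave-one-out, never random.

## Worked example

```r
library(breathvoc)
library(dplyr)

# a 43-peak library with three 2-fold asthma markers planted
lib <- peak_library(n_peaks = 43, seed = 1) |>
  set_marker_effects(c(8, 22, 36), c(asthma = 2))
design <- cohort_design(c(asthma = 20, control = 20), peaks = lib,
                        noise_sd = 1.5, seed = 42)
cohort <- simulate_cohort(design)

matrix <- process_chromatograms(cohort$chromatograms)
labels <- cohort$samples$group[match(matrix$sample_id,
                                     cohort$samples$sample_id)]
mean(rowSums(feature_matrix(matrix) > 0))   # detected peaks per chromatogram
#> [1] 43

panel <- select_subset(matrix, labels, k_max = 9, strategy = "greedy")
panel
#> Biomarker panel (asthma vs control)
#>   peaks: 8, 16, 19, 22, 26, 33, 36, 37, 38
#>   LOO accuracy 1.000, CV margin 1.619, boundary distance 0.600 (greedy search)

match_planted_peaks(matrix, lib) |>
  filter(library_id %in% c(8, 22, 36)) |>
  pull(matrix_id)                  # all three planted markers are in the panel
#> [1]  8 22 36

projection <- pca_project(matrix, model = panel$model)
projection
#> PCA projection on panel {8, 16, 19, 22, 26, 33, 36, 37, 38}
#>   PC1 36.3%, PC2 15.6% of variance; 40 samples
autoplot(projection, labels = cohort$samples)   # score plot with the boundary
```

The panel's leave-one-out accuracy of 1.000 means every held-out sample was
classified correctly during selection (an optimistic estimate — selection
bias is documented in the methods vignette); the boundary distance of 0.600
says the nearest training sample sits half a standardized unit from the
decision boundary on its correct side. All three planted markers (consensus
ids 8, 22, 36) were recovered among the nine panel slots.

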