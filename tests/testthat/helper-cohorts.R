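# fixture builders shared across test files; everything is generated in code

# small two-group cohort with three planted 2-fold markers among background
marker_design <- function(n_per_group = 10, n_background = 40, n_markers = 3,
                          effect = 2, area_cv = 0.2, noise_sd = 1, seed = 1) {
  lib <- peak_library(n_peaks = n_background + n_markers, area_cv = area_cv,
                      seed = seed)
  marker_ids <- round(seq(5, n_background + n_markers - 4,
                          length.out = n_markers))
  lib <- set_marker_effects(lib, marker_ids, c(case = effect))
  list(
    design = cohort_design(
      groups = c(case = n_per_group, control = n_per_group),
      peaks = lib, noise_sd = noise_sd, seed = seed
    ),
    marker_ids = marker_ids
  )
}

# three phenotype groups: step-1 markers place atopy between asthma and
# control; step-2 markers are atopy-specific. The peak library is fixed
# (lib_seed) so cohorts simulated with different seeds share one namespace,
# as train/test sets drawn from one instrument would.
three_group_design <- function(n_per_group = 15, n_background = 30,
                               effect = 2, area_cv = 0.2, seed = 1,
                               lib_seed = 1) {
  atopic <- "non-asthma/atopic"
  lib <- peak_library(n_peaks = n_background + 5, area_cv = area_cv,
                      seed = lib_seed)
  step1 <- c(4, 14, 24)
  step2 <- c(30, 34)
  lib <- set_marker_effects(
    lib, step1,
    list(setNames(c(effect, sqrt(effect)), c("asthma", atopic)),
         setNames(c(effect, sqrt(effect)), c("asthma", atopic)),
         setNames(c(effect, sqrt(effect)), c("asthma", atopic)))
  )
  lib <- set_marker_effects(lib, step2, setNames(effect, atopic))
  cohort_design(
    groups = setNames(rep(n_per_group, 3),
                      c("asthma", atopic, "non-asthma/non-atopic")),
    peaks = lib, seed = seed
  )
}

# simulated normalized area matrix + labels, skipping trace rendering
truth_data <- function(design) {
  coh <- simulate_cohort(design, render = FALSE)
  tm <- truth_matrix(coh)
  list(matrix = tm,
       labels = coh$samples$group[match(tm$sample_id, coh$samples$sample_id)],
       cohort = coh)
}
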