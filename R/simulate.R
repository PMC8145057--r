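# synthetic breath chromatograms with planted ground truth -------------------

#' Build a library of chromatographic peak specifications
#'
#' Generates `n_peaks` peak specifications spread over a retention-time window,
#' emulating the ~90 VOC peaks detectable in a 10-minute breath separation on a
#' short portable-GC column. Apex times sit on a jittered grid so that adjacent
#' peaks stay resolvable (spacing at least four peak widths); areas span roughly
#' an order of magnitude on a log scale. All peaks start as background (no group
#' effect); mark discriminatory peaks with [set_marker_effects()].
#'
#' @param n_peaks Number of peaks in the library.
#' @param rt_range Two-element numeric, the retention-time window (seconds)
#'   that apexes occupy.
#' @param sigma_range Range of Gaussian peak widths (SD, seconds).
#' @param height_range Range of mean apex heights (detector units); areas are
#'   derived as `height * sigma * sqrt(2*pi)`. Heights are drawn log-uniformly.
#' @param area_cv Lognormal coefficient of variation of each peak's area across
#'   samples.
#' @param seed Optional integer seed for reproducible libraries.
#' @return A tibble with one row per peak: `peak_id`, `mu_rt`, `sigma_rt`,
#'   `base_area`, `area_cv`, and a list-column `effects` of named numeric
#'   multiplicative group effects (empty for background peaks).
#' @export
#' @examples
#' lib <- peak_library(n_peaks = 20, seed = 1)
#' lib
peak_library <- function(n_peaks = 90, rt_range = c(30, 570),
                         sigma_range = c(0.8, 1.2),
                         height_range = c(30, 600),
                         area_cv = 0.2, seed = NULL) {
  if (n_peaks < 1) abort_invalid("`n_peaks` must be at least 1.")
  if (diff(rt_range) <= 0) abort_invalid("`rt_range` must be increasing.")
  if (any(sigma_range <= 0)) abort_invalid("peak widths must be positive.")
  if (area_cv < 0) abort_invalid("`area_cv` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  # jittered grid keeps neighbours >= ~4 sigma apart so planted peaks resolve
  grid <- seq(rt_range[1], rt_range[2], length.out = n_peaks)
  spacing <- if (n_peaks > 1) diff(grid[1:2]) else diff(rt_range)
  jitter_amp <- min(0.08 * spacing, 0.5)
  mu <- grid + runif(n_peaks, -jitter_amp, jitter_amp)
  sigma <- runif(n_peaks, sigma_range[1], sigma_range[2])
  height <- exp(runif(n_peaks, log(height_range[1]), log(height_range[2])))
  tibble(
    peak_id = seq_len(n_peaks),
    mu_rt = mu,
    sigma_rt = sigma,
    base_area = height * sigma * sqrt(2 * pi),
    area_cv = area_cv,
    effects = replicate(n_peaks, numeric(0), simplify = FALSE)
  )
}

#' Plant multiplicative group effects on marker peaks
#'
#' @param peaks A peak library tibble from [peak_library()].
#' @param peak_ids Integer ids of the peaks to mark.
#' @param effects Named numeric vector of multiplicative area shifts, one name
#'   per affected group (groups not named keep a multiplier of 1), or a list of
#'   such vectors (one per peak id).
#' @return The library with the `effects` column updated.
#' @export
#' @examples
#' lib <- peak_library(10, seed = 1)
#' lib <- set_marker_effects(lib, c(3, 7), c(asthma = 2))
set_marker_effects <- function(peaks, peak_ids, effects) {
  if (!all(peak_ids %in% peaks$peak_id)) {
    abort_invalid("some `peak_ids` are not in the library.")
  }
  if (!is.list(effects)) effects <- replicate(length(peak_ids), effects, simplify = FALSE)
  if (length(effects) != length(peak_ids)) {
    abort_invalid("`effects` must have one entry per peak id.")
  }
  for (i in seq_along(peak_ids)) {
    eff <- effects[[i]]
    if (is.null(names(eff)) || any(names(eff) == "") || any(eff <= 0)) {
      abort_invalid("each effect must be a named vector of positive multipliers.")
    }
    peaks$effects[[which(peaks$peak_id == peak_ids[i])]] <- eff
  }
  peaks
}

marker_ids <- function(peaks) {
  peaks$peak_id[lengths(peaks$effects) > 0]
}

#' Describe a simulated breath-sampling cohort
#'
#' Bundles everything needed to simulate a cohort of breath chromatograms:
#' group sizes, the peak library, retention-time jitter, baseline drift,
#' detector noise, peak dropout, and the acquisition grid. Defaults emulate
#' the study conditions of a portable-GC breath separation: 600 s runs sampled
#' at 4 Hz with a rigid per-sample retention shift.
#'
#' @param groups Named integer vector of samples per group, e.g.
#'   `c(asthma = 20, control = 20)`.
#' @param peaks Peak library tibble ([peak_library()]).
#' @param rt_jitter_sd SD of the rigid per-sample retention-time shift (s).
#' @param baseline List of drift parameters: `intercept`, `slope` (units per
#'   full run), `amplitude` and `period` (s) of a slow sinusoid.
#' @param noise_sd Additive white detector noise SD.
#' @param dropout_prob Per-peak probability that a peak is absent in a sample.
#' @param duration Run length in seconds.
#' @param sampling_rate Detector sampling rate, Hz.
#' @param tailing_tau Exponential tailing constant (s) for exponentially
#'   modified Gaussian peaks; 0 gives symmetric Gaussians.
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(asthma = 20, control = 20),
                          peaks = peak_library(),
                          rt_jitter_sd = 0.5,
                          baseline = list(intercept = 2, slope = 5,
                                          amplitude = 3, period = 300),
                          noise_sd = 1,
                          dropout_prob = 0,
                          duration = 600,
                          sampling_rate = 4,
                          tailing_tau = 0,
                          seed = 1L) {
  if (is.null(names(groups)) || any(groups < 1)) {
    abort_invalid("`groups` must be a named vector with all sizes >= 1.")
  }
  if (nrow(peaks) < 1) abort_invalid("the peak library is empty.")
  if (rt_jitter_sd < 0) abort_invalid("`rt_jitter_sd` must be non-negative.")
  if (noise_sd < 0) abort_invalid("`noise_sd` must be non-negative.")
  if (dropout_prob < 0 || dropout_prob >= 1) {
    abort_invalid("`dropout_prob` must be in [0, 1).")
  }
  if (duration <= 0 || sampling_rate <= 0) {
    abort_invalid("`duration` and `sampling_rate` must be positive.")
  }
  structure(list(groups = groups, peaks = peaks, rt_jitter_sd = rt_jitter_sd,
                 baseline = baseline, noise_sd = noise_sd,
                 dropout_prob = dropout_prob, duration = duration,
                 sampling_rate = sampling_rate, tailing_tau = tailing_tau,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

baseline_trace <- function(time, baseline, duration) {
  if (is.null(baseline)) return(rep(0, length(time)))
  (baseline$intercept %||% 0) +
    (baseline$slope %||% 0) * time / duration +
    (baseline$amplitude %||% 0) * sin(2 * pi * time / (baseline$period %||% Inf))
}

# Unit-area peak shape: Gaussian, or exponentially modified Gaussian when a
# positive tailing constant is supplied (written with pnorm for stability).
peak_shape <- function(time, mu, sigma, tau = 0) {
  if (tau <= 0) return(dnorm(time, mu, sigma))
  l <- 1 / tau
  z <- (mu + l * sigma^2 - time) / sigma
  l * exp(l / 2 * (2 * mu + l * sigma^2 - 2 * time) +
            stats::pnorm(z, lower.tail = FALSE, log.p = TRUE))
}

#' Simulate one breath chromatogram
#'
#' Renders a detector trace from realized peak areas: each peak contributes a
#' Gaussian (optionally exponentially modified) of the stated area centred at
#' its apex; baseline drift and additive white noise are added last.
#'
#' @param peaks Data frame with columns `mu_rt`, `sigma_rt` and `area`
#'   (realized areas, detector-units x seconds). May be empty.
#' @param duration Run length, seconds (> 0).
#' @param sampling_rate Sampling rate, Hz (> 0).
#' @param baseline Baseline drift parameters as in [cohort_design()], or
#'   `NULL` for a flat zero baseline.
#' @param noise_sd Additive white noise SD.
#' @param tailing_tau Exponential tailing constant (s); 0 = symmetric.
#' @param seed Optional integer seed (noise reproducibility).
#' @return A tibble with columns `time_s` (uniform grid starting at 0) and
#'   `intensity`, of length `duration * sampling_rate`.
#' @export
#' @examples
#' tr <- simulate_chromatogram(
#'   data.frame(mu_rt = 100, sigma_rt = 2, area = 500),
#'   duration = 200, sampling_rate = 4, noise_sd = 0.5, seed = 1
#' )
simulate_chromatogram <- function(peaks = NULL, duration = 600,
                                  sampling_rate = 4, baseline = NULL,
                                  noise_sd = 0, tailing_tau = 0, seed = NULL) {
  if (duration <= 0 || sampling_rate <= 0) {
    abort_invalid("`duration` and `sampling_rate` must be positive.")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- round(duration * sampling_rate)
  time <- (seq_len(n) - 1) / sampling_rate
  intensity <- baseline_trace(time, baseline, duration)
  if (!is.null(peaks) && nrow(peaks)) {
    for (i in seq_len(nrow(peaks))) {
      intensity <- intensity + peaks$area[i] *
        peak_shape(time, peaks$mu_rt[i], peaks$sigma_rt[i], tailing_tau)
    }
  }
  if (noise_sd > 0) intensity <- intensity + rnorm(n, sd = noise_sd)
  tibble(time_s = time, intensity = intensity)
}

#' Simulate a cohort of breath chromatograms with ground truth
#'
#' Draws, for every sample, a rigid retention-time shift, per-peak lognormal
#' areas (group effects applied multiplicatively to the mean before sampling),
#' and peak dropout; then renders each chromatogram with baseline drift and
#' detector noise. Everything planted is recorded in the returned ground
#' truth, so downstream peak detection, alignment and selection can be scored
#' against it.
#'
#' @param design A [cohort_design()].
#' @param render If `FALSE`, skip rendering the traces (the ground-truth table
#'   is identical either way); useful for selection/classification studies
#'   that work directly from true areas.
#' @return A list of class `voc_cohort` with elements
#'   * `chromatograms`: long tibble `sample_id`, `time_s`, `intensity`
#'     (`NULL` when `render = FALSE`);
#'   * `samples`: tibble `sample_id`, `group`;
#'   * `truth`: tibble `sample_id`, `group`, `peak_id`, `true_rt_s`,
#'     `true_area`, `marker` (absent peaks have `true_area = 0`);
#'   * `design`: the design used.
#' @export
#' @examples
#' d <- cohort_design(c(a = 3, b = 3), peak_library(10, seed = 2), seed = 5)
#' coh <- simulate_cohort(d)
#' dplyr::count(coh$truth, group)
simulate_cohort <- function(design, render = TRUE) {
  if (!inherits(design, "cohort_design")) {
    abort_invalid("`design` must come from cohort_design().")
  }
  peaks <- design$peaks
  if (nrow(peaks) < 1) abort_invalid("the peak library is empty.")
  set.seed(design$seed)
  markers <- marker_ids(peaks)
  groups <- design$groups
  samples <- tibble(
    group = rep(names(groups), groups),
    sample_id = sprintf("%s_%03d", gsub("[^[:alnum:]]+", "-", rep(names(groups), groups)),
                        unlist(lapply(groups, seq_len)))
  )[, c("sample_id", "group")]
  sdlog <- sqrt(log(1 + peaks$area_cv^2))
  truth <- vector("list", nrow(samples))
  shifts <- rnorm(nrow(samples), sd = design$rt_jitter_sd)
  for (s in seq_len(nrow(samples))) {
    g <- samples$group[s]
    eff <- vapply(peaks$effects, function(e) {
      if (g %in% names(e)) unname(e[[g]]) else 1
    }, numeric(1))
    # lognormal with mean = base_area * effect and CV = area_cv
    area <- peaks$base_area * eff *
      exp(rnorm(nrow(peaks), -sdlog^2 / 2, sdlog))
    if (design$dropout_prob > 0) {
      area[runif(nrow(peaks)) < design$dropout_prob] <- 0
    }
    truth[[s]] <- tibble(
      sample_id = samples$sample_id[s], group = g,
      peak_id = peaks$peak_id,
      true_rt_s = peaks$mu_rt + shifts[s],
      true_area = area,
      marker = peaks$peak_id %in% markers
    )
  }
  truth <- dplyr::bind_rows(truth)
  chroms <- NULL
  if (render) {
    pieces <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      tt <- truth[truth$sample_id == samples$sample_id[s] & truth$true_area > 0, ]
      pieces[[s]] <- simulate_chromatogram(
        data.frame(mu_rt = tt$true_rt_s, sigma_rt = peaks$sigma_rt[match(tt$peak_id, peaks$peak_id)],
                   area = tt$true_area),
        duration = design$duration, sampling_rate = design$sampling_rate,
        baseline = design$baseline, noise_sd = design$noise_sd,
        tailing_tau = design$tailing_tau
      )
    }
    names(pieces) <- samples$sample_id
    chroms <- rebind_samples(pieces)
  }
  structure(list(chromatograms = chroms, samples = samples, truth = truth,
                 design = design),
            class = "voc_cohort")
}

#' Ground-truth area matrix of a simulated cohort
#'
#' Arranges the planted per-sample true areas as a wide samples-by-peaks
#' tibble, bypassing trace rendering and preprocessing. Peak columns are named
#' by library `peak_id`.
#'
#' @param cohort A `voc_cohort` from [simulate_cohort()].
#' @param normalize Divide each sample's areas by their total (the same
#'   normalization the preprocessing chain applies)?
#' @return A wide tibble: `sample_id` then one numeric column per peak.
#' @export
truth_matrix <- function(cohort, normalize = TRUE) {
  tr <- cohort$truth
  if (normalize) {
    tr <- tr |>
      group_by(.data$sample_id) |>
      mutate(true_area = .data$true_area / sum(.data$true_area)) |>
      ungroup()
  }
  tr |>
    mutate(peak_id = as.character(.data$peak_id)) |>
    select("sample_id", "peak_id", "true_area") |>
    tidyr::pivot_wider(names_from = "peak_id", values_from = "true_area")
}
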