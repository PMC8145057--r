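# smoothing, peak detection/integration, normalization, alignment ------------

#' Smooth a chromatogram with a Savitzky-Golay filter
#'
#' Local polynomial smoothing preserves the apex position and area of
#' well-resolved peaks much better than a moving average while strongly
#' attenuating white detector noise.
#'
#' @inheritParams correct_baseline
#' @param window Odd window length in samples (>= 3, and at least
#'   `polyorder + 2` — with fewer points the local fit interpolates exactly
#'   and nothing is smoothed).
#' @param polyorder Polynomial order of the local fit.
#' @return The smoothed chromatogram, same shape as the input.
#' @export
denoise <- function(chrom, window = 9, polyorder = 3) {
  if (window %% 2 == 0) abort_invalid("`window` must be odd.")
  if (window < 3 || window < polyorder + 2) {
    abort_invalid("`window` must be >= 3 and at least `polyorder + 2`.")
  }
  pieces <- chrom_groups(chrom)
  out <- lapply(pieces, function(tr) {
    tr$intensity <- signal::sgolayfilt(tr$intensity, p = polyorder, n = window)
    tr
  })
  if ("sample_id" %in% names(chrom)) rebind_samples(out) else out[[1]]
}

#' Detect and integrate peaks in a chromatogram
#'
#' Finds local maxima whose height exceeds `snr_min` times a robust noise
#' estimate ([estimate_noise()]), keeps the taller peak when two maxima fall
#' within `min_separation` seconds, then integrates each peak between its
#' flanking valleys (or where the trace falls below `tail_frac` of the apex
#' height, whichever comes first) by the trapezoid rule. The input should be
#' baseline-corrected and smoothed first.
#'
#' @inheritParams correct_baseline
#' @param snr_min Minimum apex height, in units of the robust noise SD.
#' @param min_separation Minimum apex-to-apex distance, seconds.
#' @param tail_frac Fraction of apex height at which integration bounds stop
#'   extending outwards.
#' @param min_height_frac Absolute height floor as a fraction of the trace
#'   maximum; suppresses spurious ripples on (near) noise-free traces.
#' @param max_fwhm Maximum full width at half maximum, seconds. Chromatographic
#'   peaks on a short portable-GC column are a few seconds wide; local maxima
#'   broader than this (e.g. imperfectly removed baseline drift) are rejected.
#' @param min_area_frac Area reject threshold as a fraction of the largest
#'   detected peak area in the trace, the chromatography integrator's usual
#'   guard against integrating baseline wiggles.
#' @param noise Known noise SD in the units of the *unsmoothed* trace, either
#'   a single value or a vector named by sample id. When `NULL` it is
#'   estimated from the trace with [estimate_noise()]; on peak-dense breath
#'   chromatograms prefer the smoothing-residual estimate that
#'   [process_chromatograms()] computes, since little peak-free baseline
#'   remains for a difference-based estimate.
#' @return A peak table tibble: `sample_id` (when present in the input),
#'   `apex_rt_s`, `height`, `area`, `left_s`, `right_s`, sorted by apex time.
#'   An empty tibble is a valid result.
#' @export
#' @examples
#' tr <- simulate_chromatogram(
#'   data.frame(mu_rt = 50, sigma_rt = 1.5, area = 200),
#'   duration = 100, sampling_rate = 4
#' )
#' detect_peaks(tr)
detect_peaks <- function(chrom, snr_min = 5, min_separation = 2,
                         tail_frac = 0.005, min_height_frac = 1e-3,
                         max_fwhm = 10, min_area_frac = 1e-3, noise = NULL) {
  if (snr_min < 0) abort_invalid("`snr_min` must be non-negative.")
  if (min_separation < 0) abort_invalid("`min_separation` must be non-negative.")
  if (max_fwhm <= 0) abort_invalid("`max_fwhm` must be positive.")
  if (min_area_frac < 0 || min_area_frac >= 1) {
    abort_invalid("`min_area_frac` must be in [0, 1).")
  }
  pieces <- chrom_groups(chrom)
  noise_for <- function(id) {
    if (is.null(noise)) NULL
    else if (!is.null(names(noise))) unname(noise[[id]])
    else noise
  }
  out <- lapply(names(pieces), function(id) {
    detect_peaks_one(pieces[[id]],
                     snr_min = snr_min, min_separation = min_separation,
                     tail_frac = tail_frac, min_height_frac = min_height_frac,
                     max_fwhm = max_fwhm, min_area_frac = min_area_frac,
                     noise = noise_for(id))
  })
  names(out) <- names(pieces)
  if ("sample_id" %in% names(chrom)) {
    rebind_samples(out)
  } else {
    out[[1]]
  }
}

detect_peaks_one <- function(tr, snr_min, min_separation, tail_frac,
                             min_height_frac, max_fwhm = 10,
                             min_area_frac = 1e-3, noise = NULL) {
  y <- tr$intensity
  t <- tr$time_s
  n <- length(y)
  empty <- tibble(apex_rt_s = numeric(0), height = numeric(0),
                  area = numeric(0), left_s = numeric(0), right_s = numeric(0))
  if (n < 3 || all(y <= 0)) return(empty)
  # For smoothed traces the difference-based estimate underestimates badly
  # (adjacent noise is correlated), so floor it with the point-wise MAD of the
  # trace; on peak-dense chromatograms pass `noise` explicitly instead.
  if (is.null(noise)) noise <- max(estimate_noise(y), stats::mad(y))
  floor_h <- max(snr_min * noise, min_height_frac * max(y))
  # strict local maxima (plateaus: leftmost point)
  cand <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n]) + 1L
  cand <- cand[y[cand] >= floor_h]
  if (!length(cand)) return(empty)
  # enforce minimum separation: keep taller apex
  cand <- cand[order(y[cand], decreasing = TRUE)]
  keep <- logical(0)
  kept <- integer(0)
  for (i in cand) {
    if (all(abs(t[i] - t[kept]) >= min_separation)) kept <- c(kept, i)
  }
  kept <- sort(kept)
  dt <- t[2] - t[1]
  rows <- lapply(seq_along(kept), function(j) {
    i <- kept[j]
    h <- y[i]
    cutoff <- tail_frac * h
    # walk left to valley / cutoff / previous kept apex midpoint
    lo_lim <- if (j > 1) which.min(y[kept[j - 1]:i]) + kept[j - 1] - 1L else 1L
    l <- i
    while (l > lo_lim && y[l - 1] <= y[l] && y[l - 1] > cutoff) l <- l - 1L
    l_at_cutoff <- l > lo_lim && y[l - 1] <= cutoff
    if (l_at_cutoff) l <- l - 1L
    hi_lim <- if (j < length(kept)) which.min(y[i:kept[j + 1]]) + i - 1L else n
    r <- i
    while (r < hi_lim && y[r + 1] <= y[r] && y[r + 1] > cutoff) r <- r + 1L
    r_at_cutoff <- r < hi_lim && y[r + 1] <= cutoff
    if (r_at_cutoff) r <- r + 1L
    seg <- y[l:r]
    # Trapezoid integral minus a valley-to-valley chord. A bound that reached
    # the tail cutoff sits on the peak's own tail: nothing to remove there. A
    # bound that stopped at a valley sits on neighbouring tails (or noise):
    # subtract the part of its level exceeding the noise SD. Endpoint levels
    # are averaged over a few samples so detector noise at a single bound
    # does not leak into the area.
    lvl <- function(idx, at_cutoff) {
      if (at_cutoff) return(0)
      max(0, mean(y[max(1, idx - 2):min(n, idx + 2)]) - noise)
    }
    area <- sum((seg[-1] + seg[-length(seg)]) / 2) * dt -
      (lvl(l, l_at_cutoff) + lvl(r, r_at_cutoff)) / 2 * (t[r] - t[l])
    # full width at half maximum, bounded by the integration window
    half <- h / 2
    wl <- i
    while (wl > l && y[wl - 1] > half) wl <- wl - 1L
    wr <- i
    while (wr < r && y[wr + 1] > half) wr <- wr + 1L
    tibble(apex_rt_s = t[i], height = h, area = area,
           left_s = t[l], right_s = t[r], fwhm = t[wr] - t[wl])
  })
  res <- dplyr::bind_rows(rows)
  res <- res[res$area > 0 & res$fwhm <= max_fwhm, ]
  if (nrow(res)) res <- res[res$area >= min_area_frac * max(res$area), ]
  res$fwhm <- NULL
  res
}

#' Normalize peak areas to unit total per chromatogram
#'
#' Divides each sample's peak areas by their sum, so the areas of every
#' chromatogram sum to 1. Total-area normalization controls sample-to-sample
#' variation in exhaled volume and bag sampling, the dominant nuisance in
#' bag-collected breath.
#'
#' @param table A peak table from [detect_peaks()] (with or without a
#'   `sample_id` column).
#' @return The peak table with `area` rescaled per sample.
#' @export
normalize_areas <- function(table) {
  if (!is.data.frame(table) || nrow(table) == 0) {
    abort_invalid("`table` must contain at least one peak.")
  }
  table <- as_tibble(table)
  if ("sample_id" %in% names(table)) {
    table |>
      group_by(.data$sample_id) |>
      mutate(area = .data$area / sum(.data$area)) |>
      ungroup()
  } else {
    mutate(table, area = .data$area / sum(.data$area))
  }
}

# split a sorted apex vector into clusters: single linkage at gap > tol, then
# recursively split any cluster whose span exceeds 2 * tol or that holds two
# peaks of one sample, at its largest internal gap
split_cluster <- function(df, tol) {
  if (nrow(df) == 1) return(list(df))
  gaps <- diff(df$apex_rt_s)
  span <- df$apex_rt_s[nrow(df)] - df$apex_rt_s[1]
  dup <- anyDuplicated(df$sample_id) > 0
  if (span <= 2 * tol && !dup) return(list(df))
  if (all(gaps == 0)) {
    # identical apexes from one sample cannot be separated by time: keep the
    # larger-area peak in this cluster, spin the rest into singletons
    ord <- order(-df$area)
    return(c(list(df[ord[1], , drop = FALSE]),
             lapply(ord[-1], function(i) df[i, , drop = FALSE])))
  }
  cut <- which.max(gaps)
  c(split_cluster(df[seq_len(cut), , drop = FALSE], tol),
    split_cluster(df[-seq_len(cut), , drop = FALSE], tol))
}

#' Align peak tables across chromatograms into a consensus peak matrix
#'
#' Pools the apex times of all samples and clusters them by greedy single
#' linkage: a gap larger than `rt_tolerance` starts a new consensus peak, and
#' clusters are recursively split at their largest internal gap while their
#' span exceeds `2 * rt_tolerance` or while any sample contributes two peaks.
#' Consensus peaks are numbered 1, 2, ... by ascending median apex time; a
#' sample that lacks a consensus peak gets area 0 (a peak below detection
#' genuinely contributes ~0 area — absent values are zero-filled, never
#' imputed).
#'
#' @param tables A peak table with a `sample_id` column (typically normalized
#'   with [normalize_areas()]), or a list of single-sample peak tables whose
#'   names are the sample ids.
#' @param rt_tolerance Single-linkage gap tolerance, seconds (> 0).
#' @return A wide tibble of class `peak_matrix`: `sample_id` then one numeric
#'   area column per consensus peak, named by integer peak id. The consensus
#'   (median) retention time of every peak is stored in the `consensus_rt`
#'   attribute, retrievable with [peak_info()].
#' @export
align_chromatograms <- function(tables, rt_tolerance = 2) {
  if (rt_tolerance <= 0) abort_invalid("`rt_tolerance` must be positive.")
  if (is.data.frame(tables)) {
    if (!"sample_id" %in% names(tables)) {
      tables$sample_id <- "sample_1"
    }
    pooled <- as_tibble(tables)
  } else if (is.list(tables) && length(tables)) {
    nms <- names(tables) %||% paste0("sample_", seq_along(tables))
    pooled <- dplyr::bind_rows(lapply(tables, as_tibble), .id = "sample_id")
    pooled$sample_id <- rep(nms, vapply(tables, nrow, integer(1)))
  } else {
    abort_invalid("`tables` must be a non-empty peak table or list of them.")
  }
  if (nrow(pooled) == 0) abort_invalid("no peaks to align.")
  sample_ids <- sort(unique(pooled$sample_id))
  # deterministic pooling order regardless of input sample order
  pooled <- pooled[order(pooled$apex_rt_s, pooled$area, pooled$sample_id), ]
  gaps <- diff(pooled$apex_rt_s)
  grp <- cumsum(c(1, as.integer(gaps > rt_tolerance)))
  clusters <- unlist(
    lapply(split(pooled, grp), split_cluster, tol = rt_tolerance),
    recursive = FALSE
  )
  med <- vapply(clusters, function(d) median(d$apex_rt_s), numeric(1))
  ord <- order(med)
  clusters <- clusters[ord]
  med <- med[ord]
  k <- length(clusters)
  areas <- matrix(0, nrow = length(sample_ids), ncol = k,
                  dimnames = list(sample_ids, as.character(seq_len(k))))
  for (j in seq_len(k)) {
    cl <- clusters[[j]]
    areas[cl$sample_id, j] <- cl$area
  }
  out <- bind_cols(tibble(sample_id = sample_ids),
                   as_tibble(areas, .name_repair = "minimal"))
  attr(out, "consensus_rt") <- setNames(med, colnames(areas))
  class(out) <- c("peak_matrix", class(out))
  out
}

#' Consensus peak information of an aligned peak matrix
#'
#' @param x A `peak_matrix` from [align_chromatograms()].
#' @return A tibble with `peak_id` (integer) and `consensus_rt` (seconds).
#' @export
peak_info <- function(x) {
  rt <- attr(x, "consensus_rt")
  if (is.null(rt)) abort_invalid("`x` has no consensus retention times.")
  tibble(peak_id = as.integer(names(rt)), consensus_rt = unname(rt))
}

#' @method tidy peak_matrix
#' @export
tidy.peak_matrix <- function(x, ...) {
  long <- tidyr::pivot_longer(as_tibble(unclass(x)), -"sample_id",
                              names_to = "peak_id", values_to = "area")
  long$peak_id <- as.integer(long$peak_id)
  rt <- attr(x, "consensus_rt")
  if (!is.null(rt)) {
    long$consensus_rt <- unname(rt[as.character(long$peak_id)])
  }
  long
}

#' Numeric feature matrix of an aligned peak matrix
#'
#' Strips the `sample_id` column and returns the peak-area values as a
#' numeric matrix with sample ids as row names — the form the modelling
#' layer consumes.
#'
#' @param data A `peak_matrix` or any wide data frame of numeric features
#'   (an optional `sample_id` column becomes the row names).
#' @return A numeric matrix, samples by peaks.
#' @export
feature_matrix <- function(data) {
  df <- as.data.frame(data)
  rn <- if ("sample_id" %in% names(df)) df$sample_id else rownames(df)
  df <- df[, setdiff(names(df), "sample_id"), drop = FALSE]
  m <- as.matrix(df)
  if (!is.numeric(m)) abort_invalid("feature columns must be numeric.")
  rownames(m) <- rn
  m
}

#' Run the full preprocessing chain on a set of chromatograms
#'
#' Baseline correction, Savitzky-Golay smoothing, peak detection and
#' integration, total-area normalization, and retention-time alignment, in
#' that order.
#'
#' @param chrom Long chromatogram tibble (`sample_id`, `time_s`, `intensity`),
#'   e.g. the `chromatograms` element of [simulate_cohort()].
#' @param smoothness,asymmetry Passed to [correct_baseline()].
#' @param window,polyorder Passed to [denoise()].
#' @param snr_min,min_separation Passed to [detect_peaks()].
#' @param rt_tolerance Passed to [align_chromatograms()].
#' @return A `peak_matrix` (see [align_chromatograms()]).
#' @export
process_chromatograms <- function(chrom, smoothness = 3e7, asymmetry = 1e-4,
                                  window = 9, polyorder = 3,
                                  snr_min = 5, min_separation = 2,
                                  rt_tolerance = 2) {
  corrected <- correct_baseline(chrom, smoothness = smoothness,
                                asymmetry = asymmetry)
  # Raw-trace noise SD per sample before smoothing: on peak-dense breath
  # chromatograms almost no baseline is peak-free, so a difference-based
  # estimate is badly inflated; the smoothing-residual estimate is not.
  noise <- vapply(chrom_groups(corrected), function(tr) {
    estimate_noise(tr$intensity, method = "residual",
                   window = window, polyorder = polyorder)
  }, numeric(1))
  corrected |>
    denoise(window = window, polyorder = polyorder) |>
    detect_peaks(snr_min = snr_min, min_separation = min_separation,
                 noise = noise) |>
    normalize_areas() |>
    align_chromatograms(rt_tolerance = rt_tolerance)
}

#' Match consensus peaks to a simulation's planted peak library
#'
#' For every planted library peak, finds the consensus peak whose retention
#' time is nearest (within `tol` seconds). Used to score detection recall and
#' marker recovery against ground truth.
#'
#' @param matrix A `peak_matrix`.
#' @param peaks A peak library ([peak_library()]).
#' @param tol Maximum |consensus_rt - mu_rt| for a match, seconds.
#' @return A tibble `library_id`, `matrix_id` (`NA` when unmatched),
#'   `consensus_rt`, `mu_rt`.
#' @export
match_planted_peaks <- function(matrix, peaks, tol = 2) {
  info <- peak_info(matrix)
  res <- lapply(seq_len(nrow(peaks)), function(i) {
    d <- abs(info$consensus_rt - peaks$mu_rt[i])
    j <- which.min(d)
    if (length(j) && d[j] <= tol) {
      tibble(library_id = peaks$peak_id[i], matrix_id = info$peak_id[j],
             consensus_rt = info$consensus_rt[j], mu_rt = peaks$mu_rt[i])
    } else {
      tibble(library_id = peaks$peak_id[i], matrix_id = NA_integer_,
             consensus_rt = NA_real_, mu_rt = peaks$mu_rt[i])
    }
  })
  dplyr::bind_rows(res)
}
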