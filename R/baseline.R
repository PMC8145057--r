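# asymmetric least squares baseline ------------------------------------------

# On pure noise the asymmetric weights make the fitted curve settle below the
# true baseline by u(p) * sigma, where u solves the weighted-mean balance
# p E[(y-z)+] = (1-p) E[(z-y)+] for standard Gaussian y. Computed once per
# call and added back so peak-free regions come out zero-mean.
als_noise_offset <- function(p) {
  bal <- function(u) {
    p * (dnorm(u) - u * stats::pnorm(u, lower.tail = FALSE)) -
      (1 - p) * (dnorm(u) + u * stats::pnorm(u))
  }
  stats::uniroot(bal, c(-6, 0), tol = 1e-9)$root
}

# Penalized asymmetric smoother: minimise sum w_i (y_i - z_i)^2 + lambda ||D2 z||^2
# with w_i small above the current baseline and ~1 below, iterated to
# convergence. Peaks (points above baseline) barely pull the fit, so z tracks
# the slowly varying background under them.
als_baseline <- function(y, lambda = 1e6, p = 0.001, maxit = 12) {
  m <- length(y)
  D <- Matrix::bandSparse(m - 2, m,
                          k = 0:2,
                          diagonals = list(rep(1, m - 2), rep(-2, m - 2), rep(1, m - 2)))
  DtD <- lambda * Matrix::crossprod(D)
  w <- rep(1, m)
  z <- y
  for (it in seq_len(maxit)) {
    W <- Matrix::Diagonal(m, w)
    z_new <- as.numeric(Matrix::solve(Matrix::forceSymmetric(W + DtD), w * y))
    w_new <- ifelse(y > z_new, p, 1 - p)
    done <- all(w_new == w)
    z <- z_new
    w <- w_new
    if (done) break
  }
  z
}

#' Baseline-correct a chromatogram
#'
#' Removes slowly varying background (column bleed, detector drift) with an
#' asymmetric penalized least-squares smoother: the baseline is a stiff smooth
#' curve fitted mostly to points below it, so peaks — which rise above — are
#' left intact while drift is subtracted. A rolling-minimum fallback is
#' available for traces whose baseline is not smooth.
#'
#' @param chrom A chromatogram tibble (`time_s`, `intensity`), or a long tibble
#'   with a `sample_id` column holding several chromatograms.
#' @param smoothness Stiffness penalty `lambda` of the smoother; larger values
#'   give flatter baselines. The default (`3e7`) keeps the baseline too stiff
#'   to dip into the valleys between peaks of a peak-dense 600 s / 4 Hz breath
#'   trace (which would eat peak area) while still following drift on the
#'   tens-of-seconds scale.
#' @param asymmetry Weight `p` given to points above the baseline (those below
#'   get `1 - p`); must be in (0, 0.5). Small values press the fit onto the
#'   lower envelope of the trace.
#' @param method `"als"` (default) or `"rolling_min"` (rolling minimum of the
#'   trace, smoothed, using a window of `window_s` seconds).
#' @param window_s Rolling-minimum window, seconds (only for
#'   `method = "rolling_min"`).
#' @return The chromatogram with the estimated baseline subtracted, same shape
#'   as the input.
#' @export
#' @examples
#' tr <- simulate_chromatogram(
#'   data.frame(mu_rt = 50, sigma_rt = 2, area = 300),
#'   duration = 100, sampling_rate = 4,
#'   baseline = list(intercept = 5, slope = 10)
#' )
#' flat <- correct_baseline(tr)
correct_baseline <- function(chrom, smoothness = 3e7, asymmetry = 1e-4,
                             method = c("als", "rolling_min"), window_s = 30) {
  method <- match.arg(method)
  if (smoothness <= 0) abort_invalid("`smoothness` must be positive.")
  if (asymmetry <= 0 || asymmetry >= 0.5) {
    abort_invalid("`asymmetry` must be in (0, 0.5).")
  }
  pieces <- chrom_groups(chrom)
  out <- lapply(pieces, function(tr) {
    if (nrow(tr) < 10) abort_invalid("chromatogram must have at least 10 points.")
    base <- switch(method,
      als = als_baseline(tr$intensity, lambda = smoothness, p = asymmetry) -
        als_noise_offset(asymmetry) *
          estimate_noise(tr$intensity, method = "residual"),
      rolling_min = rolling_min_baseline(tr, window_s)
    )
    tr$intensity <- tr$intensity - base
    tr
  })
  if ("sample_id" %in% names(chrom)) rebind_samples(out) else out[[1]]
}

rolling_min_baseline <- function(tr, window_s) {
  dt <- tr$time_s[2] - tr$time_s[1]
  k <- max(3L, round(window_s / dt))
  if (k %% 2 == 0) k <- k + 1L
  n <- length(tr$intensity)
  half <- k %/% 2
  padded <- c(rep(tr$intensity[1], half), tr$intensity, rep(tr$intensity[n], half))
  mins <- vapply(seq_len(n), function(i) min(padded[i:(i + k - 1)]), numeric(1))
  # smooth the staircase with a moving average of the same width
  as.numeric(stats::filter(c(rep(mins[1], half), mins, rep(mins[n], half)),
                           rep(1 / k, k), sides = 2))[(half + 1):(half + n)]
}
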