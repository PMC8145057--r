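# input validation helpers ---------------------------------------------------

abort_invalid <- function(msg) {
  abort(msg, class = "breathvoc_invalid")
}

# Coerce a single-sample chromatogram argument to a tibble with time_s /
# intensity columns. Accepts a two-column data frame in that order or one
# with named columns.
as_chromatogram <- function(x, arg = "chrom") {
  if (!is.data.frame(x)) {
    abort_invalid(sprintf("`%s` must be a data frame with time_s and intensity columns.", arg))
  }
  if (!all(c("time_s", "intensity") %in% names(x)) && ncol(x) >= 2) {
    names(x)[1:2] <- c("time_s", "intensity")
  }
  if (!all(c("time_s", "intensity") %in% names(x))) {
    abort_invalid(sprintf("`%s` must have columns time_s and intensity.", arg))
  }
  if (!all(is.finite(x$intensity))) {
    abort_invalid(sprintf("`%s` intensity values must all be finite.", arg))
  }
  as_tibble(x)
}

# Split a long multi-sample chromatogram tibble into per-sample pieces; a
# bare two-column trace is treated as a single anonymous sample.
chrom_groups <- function(x, arg = "chrom") {
  x <- as_tibble(x)
  if (!"sample_id" %in% names(x)) {
    return(list(sample_1 = as_chromatogram(x, arg)))
  }
  ids <- unique(x$sample_id)
  out <- lapply(ids, function(id) {
    as_chromatogram(x[x$sample_id == id, setdiff(names(x), "sample_id")], arg)
  })
  names(out) <- ids
  out
}

rebind_samples <- function(pieces) {
  dplyr::bind_rows(pieces, .id = "sample_id")
}

#' Robust noise level of a chromatogram trace
#'
#' Estimates the additive white-noise SD of an *unsmoothed* trace. The
#' `"diff"` method uses the median absolute deviation of the first difference
#' divided by `sqrt(2)` (diff of iid noise has variance `2 * sd^2`); it is
#' robust to occasional peaks but inflated on peak-dense breath chromatograms
#' where little peak-free baseline remains. The `"residual"` method uses the
#' MAD of the residual of a stiff Savitzky-Golay fit, rescaled by the
#' residual-operator variance; peaks are smooth on the filter's scale and
#' drop out, so it stays calibrated however dense the trace. The
#' preprocessing chain uses `"residual"` on the baseline-corrected trace.
#'
#' @param intensity Numeric vector of detector intensities (unsmoothed).
#' @param method `"diff"` or `"residual"`.
#' @param window,polyorder Savitzky-Golay parameters of the `"residual"`
#'   method.
#' @return A single non-negative number, the estimated noise SD.
#' @export
#' @examples
#' estimate_noise(rnorm(1000, sd = 2))
#' estimate_noise(rnorm(1000, sd = 2), method = "residual")
estimate_noise <- function(intensity, method = c("diff", "residual"),
                           window = 9, polyorder = 3) {
  method <- match.arg(method)
  if (method == "diff") {
    stats::mad(diff(intensity)) / sqrt(2)
  } else {
    cf <- signal::sgolay(p = polyorder, n = window)[(window + 1) %/% 2, ]
    k <- sqrt(1 - 2 * cf[(window + 1) %/% 2] + sum(cf^2))
    stats::mad(intensity -
                 signal::sgolayfilt(intensity, p = polyorder, n = window)) / k
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
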