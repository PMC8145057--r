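# plain-text interchange: chromatograms, peak tables, aligned matrices -------

#' Read / write chromatograms as two-column CSV
#'
#' Chromatograms travel as CSV with columns `time_s`, `intensity`. Sample
#' metadata (sample id, group labels, simulation seed) goes in a JSON-style
#' key/value sidecar next to the trace when supplied.
#'
#' @param file Path to the CSV.
#' @return `read_chromatogram()`: a tibble `time_s`, `intensity`.
#' @export
read_chromatogram <- function(file) {
  as_chromatogram(readr::read_csv(file, show_col_types = FALSE), "file")
}

#' @rdname read_chromatogram
#' @param chrom A single-sample chromatogram tibble.
#' @param metadata Optional named list written as a `.meta.json`-style sidecar
#'   (one `key: value` per line) next to `file`.
#' @return `write_chromatogram()`: the input, invisibly.
#' @export
write_chromatogram <- function(chrom, file, metadata = NULL) {
  chrom <- as_chromatogram(chrom)
  readr::write_csv(chrom[, c("time_s", "intensity")], file)
  if (!is.null(metadata)) {
    side <- paste0(sub("\\.csv$", "", file), ".meta.json")
    writeLines(paste0(
      "{\n",
      paste(sprintf('  "%s": %s', names(metadata),
                    vapply(metadata, function(v) {
                      if (is.numeric(v)) format(v) else sprintf('"%s"', v)
                    }, character(1))),
            collapse = ",\n"),
      "\n}"
    ), side)
  }
  invisible(chrom)
}

#' Write / read an aligned peak matrix as CSV
#'
#' The matrix is written with one row per sample (`sample_id` first column,
#' peak-id-named area columns); consensus retention times go to a companion
#' `<file>_peaks.csv` with columns `peak_id`, `consensus_rt`.
#'
#' @param matrix A `peak_matrix` from [align_chromatograms()].
#' @param file Path of the matrix CSV.
#' @return `write_peak_matrix()`: the path, invisibly. `read_peak_matrix()`:
#'   the reconstructed `peak_matrix`.
#' @export
write_peak_matrix <- function(matrix, file) {
  readr::write_csv(as_tibble(unclass(matrix)), file)
  readr::write_csv(peak_info(matrix),
                   paste0(sub("\\.csv$", "", file), "_peaks.csv"))
  invisible(file)
}

#' @rdname write_peak_matrix
#' @export
read_peak_matrix <- function(file) {
  out <- readr::read_csv(file, show_col_types = FALSE)
  info <- readr::read_csv(paste0(sub("\\.csv$", "", file), "_peaks.csv"),
                          show_col_types = FALSE)
  attr(out, "consensus_rt") <- setNames(info$consensus_rt,
                                        as.character(info$peak_id))
  class(out) <- c("peak_matrix", class(out))
  out
}
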