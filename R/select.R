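# biomarker panel search: LOO accuracy, margin tie-break ---------------------

# Fast leave-one-out pass. Returns the held-out accuracy and the
# cross-validated margin: the mean over folds of the held-out sample's signed
# distance to its fold model's boundary (positive on its own class's side).
# The mean — not the minimum — is used because a held-out minimum is owned by
# the single hardest sample, which a genuinely informative peak need not
# help, while the mean tracks class separation. Class assignments are
# invariant to affine feature standardization, so accuracy is valid on any
# scaling; pass standardized features when the margin is used (it is
# scale-dependent).
loo_core <- function(X, y, shrinkage) {
  n <- nrow(X)
  correct <- 0L
  margin <- 0
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (all(yi == yi[1])) next  # degenerate fold: count as wrong
    core <- lda_core(X[-i, , drop = FALSE], yi, shrinkage)
    s <- sum(X[i, ] * core$w) + core$b
    if ((s > 0) == (y[i] == 1L)) correct <- correct + 1L
    margin <- margin + (if (y[i] == 1L) s else -s) / sqrt(sum(core$w^2))
  }
  list(accuracy = correct / n, margin = margin / n)
}

loo_accuracy_core <- function(X, y, shrinkage) {
  loo_core(X, y, shrinkage)$accuracy
}

#' Leave-one-out cross-validated LDA accuracy of a peak subset
#'
#' Each sample in turn is held out, the discriminant is refitted on the rest,
#' and the held-out sample is classified; the returned value is the fraction
#' classified correctly. Deterministic: no random fold assignment at the
#' n ~ 45 sample sizes of breath studies.
#'
#' @inheritParams fit_lda
#' @param subset Peak ids (column names) forming the candidate panel.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 2), 20))
#' colnames(x) <- c("1", "2")
#' cv_accuracy(x, rep(c("a", "b"), each = 20), subset = "1")
cv_accuracy <- function(data, labels, subset = NULL, shrinkage = 0.1) {
  if (!is.null(subset) && length(subset) == 0) {
    abort_invalid("`subset` must name at least one peak.")
  }
  X <- resolve_subset(data, subset)
  if (ncol(X) == 0) abort_invalid("`data` has no feature columns.")
  f <- check_labels(labels, nrow(X))
  loo_accuracy_core(X, as.integer(f) - 1L, shrinkage)
}

# lexicographic (accuracy, margin) improvement
beats <- function(acc1, mar1, acc0, mar0) {
  acc1 > acc0 || (acc1 == acc0 && mar1 > mar0)
}

#' Select an optimal discriminatory peak subset
#'
#' Searches peak subsets of size at most `k_max` for the panel with maximum
#' leave-one-out LDA accuracy ([cv_accuracy()]); ties are broken by the
#' maximum cross-validated margin — the mean over held-out samples of their
#' signed distance to the fold model's decision boundary, computed on
#' globally standardized features — then by smaller panel size, then by
#' lexicographic peak-id order, so the result is deterministic. The
#' cross-validated margin is the held-out analogue of [boundary_distance()]:
#' unlike the training-set minimum margin, it cannot be inflated by
#' memorizing noise peaks, so redundant true markers outrank background
#' peaks once accuracy saturates. The training-set [boundary_distance()] of
#' the winning panel is reported alongside.
#'
#' Two search strategies are available. `"exhaustive"` enumerates every subset
#' (feasible only for small peak counts); `"greedy"` grows the panel by the
#' best single addition under the same (accuracy, margin) ordering and stops
#' when no addition improves it. `"auto"` picks exhaustive when there are at
#' most 20 candidate peaks and `k_max <= 4`, greedy otherwise.
#'
#' @inheritParams fit_lda
#' @param k_max Maximum panel size (>= 1).
#' @param strategy `"auto"`, `"exhaustive"` or `"greedy"`.
#' @param candidates Optional peak ids to restrict the search to (default:
#'   every feature column).
#' @param comparison Optional label describing the contrast (stored in the
#'   result).
#' @return An object of class `biomarker_panel`: `peak_ids` (character, in
#'   ascending id order), `cv_accuracy`, `cv_margin` (the tie-breaking
#'   criterion), `boundary_distance` (training-set margin of the fitted
#'   panel), the fitted `model` (`voc_lda` on the panel), `comparison` and
#'   `strategy`.
#' @export
#' @examples
#' set.seed(1)
#' x <- cbind(c(rnorm(15), rnorm(15, 3)), matrix(rnorm(90), 30))
#' colnames(x) <- as.character(1:4)
#' select_subset(x, rep(c("a", "b"), each = 15), k_max = 2)
select_subset <- function(data, labels, k_max = 5,
                          strategy = c("auto", "exhaustive", "greedy"),
                          candidates = NULL, shrinkage = 0.1,
                          comparison = NULL) {
  strategy <- match.arg(strategy)
  if (k_max < 1) abort_invalid("`k_max` must be at least 1.")
  X <- resolve_subset(data, candidates)
  f <- check_labels(labels, nrow(X))
  y <- as.integer(f) - 1L
  ids <- colnames(X)
  if (is.null(ids)) {
    ids <- as.character(seq_len(ncol(X)))
    colnames(X) <- ids
  }
  # order candidate ids numerically when possible for stable tie-breaking
  num <- suppressWarnings(as.numeric(ids))
  ids <- if (!anyNA(num)) ids[order(num)] else sort(ids)
  X <- X[, ids, drop = FALSE]
  if (strategy == "auto") {
    strategy <- if (length(ids) <= 20 && k_max <= 4) "exhaustive" else "greedy"
  }
  k_max <- min(k_max, length(ids))
  # LOO classifications are scale-invariant; margins are not, so the search
  # runs on globally standardized features
  Z <- standardize_cols(X)

  score_subset <- function(cols) {
    r <- loo_core(Z[, cols, drop = FALSE], y, shrinkage)
    list(cols = cols, acc = r$accuracy, mar = r$margin)
  }
  best <- list(cols = NULL, acc = -Inf, mar = -Inf)
  if (strategy == "exhaustive") {
    for (k in seq_len(k_max)) {
      sets <- combn(length(ids), k)
      for (j in seq_len(ncol(sets))) {
        cand <- score_subset(sets[, j])
        if (beats(cand$acc, cand$mar, best$acc, best$mar)) best <- cand
      }
    }
  } else {
    current <- integer(0)
    repeat {
      if (length(current) >= k_max) break
      remaining <- setdiff(seq_along(ids), current)
      step <- list(cols = NULL, acc = -Inf, mar = -Inf)
      for (j in remaining) {
        cand <- score_subset(c(current, j))
        if (beats(cand$acc, cand$mar, step$acc, step$mar)) step <- cand
      }
      if (!beats(step$acc, step$mar, best$acc, best$mar)) break
      current <- step$cols
      best <- step
    }
  }
  panel_ids <- ids[sort(best$cols)]
  model <- fit_lda(X, f, subset = panel_ids, shrinkage = shrinkage)
  structure(list(
    peak_ids = panel_ids,
    cv_accuracy = best$acc,
    cv_margin = best$mar,
    boundary_distance = boundary_distance(model, X, f),
    model = model,
    comparison = comparison %||% paste(levels(f), collapse = " vs "),
    strategy = strategy,
    k_max = k_max
  ), class = "biomarker_panel")
}

#' @export
print.biomarker_panel <- function(x, ...) {
  cat("Biomarker panel (", x$comparison, ")\n", sep = "")
  cat("  peaks:", paste(x$peak_ids, collapse = ", "), "\n")
  cat(sprintf("  LOO accuracy %.3f, CV margin %.3f, boundary distance %.3f (%s search)\n",
              x$cv_accuracy, x$cv_margin, x$boundary_distance, x$strategy))
  invisible(x)
}

#' @method tidy biomarker_panel
#' @export
tidy.biomarker_panel <- function(x, ...) {
  tidy(x$model)
}

#' @method glance biomarker_panel
#' @export
glance.biomarker_panel <- function(x, ...) {
  tibble(comparison = x$comparison,
         n_peaks = length(x$peak_ids),
         peak_ids = paste(x$peak_ids, collapse = ","),
         cv_accuracy = x$cv_accuracy,
         cv_margin = x$cv_margin,
         boundary_distance = x$boundary_distance,
         strategy = x$strategy)
}
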