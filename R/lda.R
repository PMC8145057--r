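# regularized two-class linear discriminant ----------------------------------

# Minimal fitting core used in the leave-one-out and subset-search loops.
# X: numeric matrix, y: 0/1 integer vector (both classes present, all finite).
# Pooled within-class covariance shrunk toward its diagonal: subsets are drawn
# from ~100 peaks at n ~ 45, so the pooled estimate needs stabilising.
lda_core <- function(X, y, shrinkage = 0.1) {
  X0 <- X[y == 0L, , drop = FALSE]
  X1 <- X[y == 1L, , drop = FALSE]
  m0 <- colMeans(X0)
  m1 <- colMeans(X1)
  c0 <- sweep(X0, 2, m0)
  c1 <- sweep(X1, 2, m1)
  S <- (crossprod(c0) + crossprod(c1)) / (nrow(X) - 2)
  if (shrinkage > 0) {
    S <- (1 - shrinkage) * S + shrinkage * diag(diag(S), ncol(X))
  }
  diag(S) <- diag(S) + 1e-10 * (mean(diag(S)) + 1e-12)
  w <- solve(S, m1 - m0)
  list(w = w, b = -sum(w * (m0 + m1)) / 2, m0 = m0, m1 = m1)
}

# z-score columns; zero-variance columns pass through unscaled
standardize_cols <- function(X) {
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  sweep(sweep(X, 2, colMeans(X)), 2, scl, "/")
}

check_labels <- function(labels, n) {
  if (length(labels) != n) {
    abort_invalid("`labels` must have one entry per sample.")
  }
  f <- factor(labels)
  if (nlevels(f) != 2) {
    abort_invalid("exactly two classes are required.")
  }
  f
}

resolve_subset <- function(data, subset) {
  m <- feature_matrix(data)
  if (is.null(subset)) return(m)
  subset <- as.character(subset)
  missing <- setdiff(subset, colnames(m))
  if (length(missing)) {
    abort_invalid(paste0("unknown peak ids: ", paste(missing, collapse = ", ")))
  }
  m[, subset, drop = FALSE]
}

#' Fit a two-class linear discriminant on peak areas
#'
#' Features are standardized (z-score, training statistics) and a linear
#' discriminant is fitted with the pooled within-class covariance shrunk
#' toward its diagonal (`shrinkage`), giving a decision value
#' `w' z + b` that is positive for the second factor level. The decision
#' threshold is the midpoint between the projected class means (equal priors).
#'
#' @param data Feature table: a `peak_matrix`, or any data frame / matrix of
#'   numeric features (a `sample_id` column is ignored as a feature).
#' @param labels Two-level class labels, one per row.
#' @param subset Optional peak ids (column names) to restrict to.
#' @param shrinkage Shrinkage weight toward the diagonal of the pooled
#'   covariance, in `[0, 1]`.
#' @param standardize Z-score the features with training statistics first?
#'   Standardization does not change the fitted classifications, only the
#'   scale on which margins are measured.
#' @return An object of class `voc_lda`: weights `w` and intercept `b` in
#'   standardized feature space, the standardization `center`/`scale`, the
#'   class `levels` (second level = positive side), and per-class means in
#'   discriminant space.
#' @export
#' @examples
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 1.5), 20))
#' colnames(x) <- c("1", "2")
#' fit <- fit_lda(x, rep(c("ctrl", "case"), each = 20))
#' tidy(fit)
fit_lda <- function(data, labels, subset = NULL, shrinkage = 0.1,
                    standardize = TRUE) {
  X <- resolve_subset(data, subset)
  f <- check_labels(labels, nrow(X))
  if (nrow(X) <= 2) abort_invalid("need more than two samples.")
  if (shrinkage < 0 || shrinkage > 1) abort_invalid("`shrinkage` must be in [0, 1].")
  center <- if (standardize) colMeans(X) else rep(0, ncol(X))
  scl <- if (standardize) apply(X, 2, sd) else rep(1, ncol(X))
  scl[scl == 0 | !is.finite(scl)] <- 1
  Z <- sweep(sweep(X, 2, center), 2, scl, "/")
  y <- as.integer(f) - 1L
  core <- lda_core(Z, y, shrinkage)
  score <- drop(Z %*% core$w) + core$b
  structure(list(
    levels = levels(f),
    features = colnames(X),
    center = center, scale = scl,
    w = core$w, b = core$b,
    class_means = c(mean(score[y == 0L]), mean(score[y == 1L])),
    shrinkage = shrinkage,
    n = nrow(X)
  ), class = "voc_lda")
}

lda_scores <- function(object, data) {
  X <- resolve_subset(data, object$features)
  Z <- sweep(sweep(X, 2, object$center), 2, object$scale, "/")
  drop(Z %*% object$w) + object$b
}

#' Predict from a fitted linear discriminant
#'
#' @param object A `voc_lda` from [fit_lda()].
#' @param newdata Feature table covering the model's peaks.
#' @param type `"class"` for labels, `"score"` for the raw decision value
#'   `w'z + b`, `"distance"` for the signed Euclidean distance to the decision
#'   boundary (score divided by `||w||`).
#' @param ... Unused.
#' @return A vector with one entry per row of `newdata`.
#' @export
predict.voc_lda <- function(object, newdata, type = c("class", "score", "distance"),
                            ...) {
  type <- match.arg(type)
  s <- lda_scores(object, newdata)
  switch(type,
    class = object$levels[(s > 0) + 1L],
    score = s,
    distance = s / sqrt(sum(object$w^2))
  )
}

#' Minimum signed margin of training samples to the decision boundary
#'
#' The boundary distance is the minimum, over the given samples, of the signed
#' Euclidean distance to the LDA decision hyperplane along the unit-norm
#' discriminant axis, the sign being positive when the sample lies on its own
#' class's side. It is positive exactly when every sample is correctly
#' classified, and is the tie-breaking criterion of [select_subset()]: among
#' equally accurate panels, the one holding the data farthest from its
#' boundary wins.
#'
#' @param model A fitted `voc_lda`.
#' @param data Feature table (typically the training data).
#' @param labels True labels for `data`, using the model's levels.
#' @return A single number (negative if any sample is misclassified).
#' @export
boundary_distance <- function(model, data, labels) {
  d <- predict(model, data, type = "distance")
  f <- factor(labels, levels = model$levels)
  if (anyNA(f)) abort_invalid("`labels` contain levels unknown to the model.")
  sgn <- ifelse(as.integer(f) == 2L, 1, -1)
  min(sgn * d)
}

#' @export
print.voc_lda <- function(x, ...) {
  cat("Two-class linear discriminant (", x$levels[1], " vs ", x$levels[2],
      ")\n", sep = "")
  cat("  peaks:", paste(x$features, collapse = ", "), "\n")
  cat("  n =", x$n, " shrinkage =", x$shrinkage, "\n")
  invisible(x)
}

#' @method tidy voc_lda
#' @export
tidy.voc_lda <- function(x, ...) {
  tibble(term = x$features, weight = unname(x$w),
         center = unname(x$center), scale = unname(x$scale))
}

#' @method glance voc_lda
#' @export
glance.voc_lda <- function(x, ...) {
  tibble(n = x$n, n_peaks = length(x$features),
         shrinkage = x$shrinkage,
         class_separation = diff(x$class_means) / sqrt(sum(x$w^2)))
}
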