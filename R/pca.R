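# PCA score plots with the LDA boundary mapped into the PC plane -------------

#' Project samples restricted to a biomarker panel onto principal components
#'
#' Standard PCA on the z-scored panel columns; the first two score columns are
#' the visualization plane. When a fitted LDA model on the same panel is
#' supplied, its decision hyperplane is re-expressed as a straight line in the
#' PC1-PC2 plane (the image of the hyperplane restricted to that subspace).
#' Loading signs are fixed so each loading vector's largest-magnitude element
#' is positive, making the projection deterministic.
#'
#' @param data Feature table (`peak_matrix` or data frame / matrix).
#' @param panel Peak ids to restrict to (>= 2); defaults to the model's peaks,
#'   or to all feature columns when neither is given.
#' @param model Optional fitted `voc_lda` on the same peaks, providing the
#'   boundary line.
#' @return An object of class `voc_projection`:
#'   * `scores`: tibble `sample_id`, `PC1`, `PC2`;
#'   * `loadings`: panel-by-PC matrix;
#'   * `var_explained`: fractions of variance, non-increasing, summing to 1;
#'   * `boundary`: list `a1`, `a2`, `b` with the line `a1*PC1 + a2*PC2 + b = 0`
#'     (`NULL` without a model);
#'   * `panel`, `center`, `scale` of the standardization.
#' @export
#' @examples
#' x <- matrix(rnorm(60), 20); colnames(x) <- as.character(1:3)
#' pr <- pca_project(x)
#' pr$var_explained
pca_project <- function(data, panel = NULL, model = NULL) {
  panel <- panel %||% model$features
  X <- resolve_subset(data, panel)
  if (ncol(X) < 2) abort_invalid("the panel must contain at least 2 peaks.")
  if (nrow(X) < 3) abort_invalid("need at least 3 samples.")
  scl <- apply(X, 2, sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  ctr <- colMeans(X)
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  pc <- prcomp(Z, center = FALSE, scale. = FALSE)
  # sign convention: largest-|.| element of each loading vector positive
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  pc$rotation <- sweep(pc$rotation, 2, flip, "*")
  pc$x <- sweep(pc$x, 2, flip, "*")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  boundary <- NULL
  if (!is.null(model)) {
    if (!setequal(model$features, colnames(X))) {
      abort_invalid("`model` was fitted on different peaks than `panel`.")
    }
    w <- model$w[match(colnames(X), model$features)]
    # hyperplane in raw space: sum(w * (x - mc)/sc) + b = 0
    w_raw <- w / model$scale[match(colnames(X), model$features)]
    b_raw <- model$b - sum(w_raw * model$center[match(colnames(X), model$features)])
    # into this projection's standardized coords z = (x - ctr)/scl
    a_full <- w_raw * scl
    b2 <- b_raw + sum(w_raw * ctr)
    a <- drop(crossprod(pc$rotation[, 1:2, drop = FALSE], a_full))
    boundary <- list(a1 = a[1], a2 = if (length(a) > 1) a[2] else 0, b = b2)
  }
  rn <- rownames(X) %||% paste0("sample_", seq_len(nrow(X)))
  structure(list(
    scores = tibble(sample_id = rn,
                    PC1 = unname(pc$x[, 1]),
                    PC2 = if (ncol(pc$x) > 1) unname(pc$x[, 2])
                          else rep(0, nrow(X))),
    loadings = pc$rotation,
    var_explained = ve,
    boundary = boundary,
    panel = colnames(X),
    center = ctr, scale = scl
  ), class = "voc_projection")
}

#' Side of the boundary line for projected samples
#'
#' @param projection A `voc_projection` with a boundary.
#' @param scores Optional score tibble (defaults to the projection's own).
#' @return `"positive"`/`"negative"` per sample: the sign of
#'   `a1*PC1 + a2*PC2 + b`. The positive side corresponds to the LDA model's
#'   second class level.
#' @export
boundary_side <- function(projection, scores = NULL) {
  if (is.null(projection$boundary)) abort_invalid("projection has no boundary.")
  s <- scores %||% projection$scores
  v <- projection$boundary$a1 * s$PC1 + projection$boundary$a2 * s$PC2 +
    projection$boundary$b
  ifelse(v > 0, "positive", "negative")
}

#' Project new samples into an existing PC plane
#'
#' @param projection A `voc_projection`.
#' @param data Feature table covering the projection's panel.
#' @return A tibble `sample_id`, `PC1`, `PC2`.
#' @export
project_samples <- function(projection, data) {
  X <- resolve_subset(data, projection$panel)
  Z <- sweep(sweep(X, 2, projection$center), 2, projection$scale, "/")
  s <- Z %*% projection$loadings[, 1:2, drop = FALSE]
  rn <- rownames(X) %||% paste0("sample_", seq_len(nrow(X)))
  tibble(sample_id = rn, PC1 = unname(s[, 1]), PC2 = unname(s[, 2]))
}

#' @export
print.voc_projection <- function(x, ...) {
  cat("PCA projection on panel {", paste(x$panel, collapse = ", "), "}\n",
      sep = "")
  ve2 <- if (length(x$var_explained) > 1) x$var_explained[2] else 0
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of variance; %d samples\n",
              100 * x$var_explained[1], 100 * ve2, nrow(x$scores)))
  invisible(x)
}

#' @method tidy voc_projection
#' @export
tidy.voc_projection <- function(x, ...) {
  x$scores
}

#' Score plot of a projection with its decision boundary
#'
#' Scatter plot of PC1 vs PC2, optionally coloured by group, with the mapped
#' LDA boundary drawn as a line (the study's score plots mark it in yellow).
#'
#' @param object A `voc_projection`.
#' @param labels Optional per-sample group labels (same order as the scores)
#'   or a data frame with `sample_id` and `group` columns to join.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voc_projection
#' @export
autoplot.voc_projection <- function(object, labels = NULL, ...) {
  df <- object$scores
  if (!is.null(labels)) {
    if (is.data.frame(labels)) {
      df <- left_join(df, labels, by = "sample_id")
    } else {
      df$group <- labels
    }
  }
  ve2 <- if (length(object$var_explained) > 1) object$var_explained[2] else 0
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * ve2)
    ) +
    ggplot2::theme_minimal()
  p <- if ("group" %in% names(df)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group, shape = .data$group))
  } else {
    p + ggplot2::geom_point()
  }
  bd <- object$boundary
  if (!is.null(bd) && abs(bd$a2) > 1e-12) {
    p <- p + ggplot2::geom_abline(intercept = -bd$b / bd$a2,
                                  slope = -bd$a1 / bd$a2,
                                  colour = "gold3", linewidth = 1)
  } else if (!is.null(bd) && abs(bd$a1) > 1e-12) {
    p <- p + ggplot2::geom_vline(xintercept = -bd$b / bd$a1,
                                 colour = "gold3", linewidth = 1)
  }
  p
}
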