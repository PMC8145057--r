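# two-step hierarchical phenotyping, subgroup panels, trajectories -----------

#' Validate and derive subject metadata flags
#'
#' Recomputes the dichotomous clinical flags from the raw measurements, never
#' trusting pre-computed columns: `obese` is BMI >= 30 kg/m^2 and `eos_high`
#' is blood eosinophils >= 0.3 x 10^9 cells/L.
#'
#' @param data A data frame with at least `sample_id`; recognised columns are
#'   `asthma`, `atopic`, `ics_treatment` (logical), `bmi` (kg/m^2),
#'   `blood_eos` (10^9 cells/L), `uri_state` (`"baseline"` or `"ill"`),
#'   `subject_id` and `visit` (for longitudinal samples).
#' @return The tibble with `obese` and `eos_high` (re)derived.
#' @export
#' @examples
#' subject_metadata(data.frame(sample_id = "s1", bmi = 30, blood_eos = 0.29))
subject_metadata <- function(data) {
  if (!is.data.frame(data) || !"sample_id" %in% names(data)) {
    abort_invalid("`data` must be a data frame with a sample_id column.")
  }
  md <- as_tibble(data)
  if ("bmi" %in% names(md)) md$obese <- md$bmi >= 30
  if ("blood_eos" %in% names(md)) md$eos_high <- md$blood_eos >= 0.3
  if ("uri_state" %in% names(md) &&
      !all(md$uri_state %in% c("baseline", "ill", NA))) {
    abort_invalid('`uri_state` must be "baseline" or "ill".')
  }
  md
}

#' Labels used by the two-step classifier
#' @export
phenotype_levels <- c("asthma", "non-asthma/atopic", "non-asthma/non-atopic")

#' Fit the two-step hierarchical phenotype rule
#'
#' Step 1 is a panel separating asthma from non-asthma/non-atopic subjects
#' (atopic controls are excluded from its training; their step-1 profile
#' typically falls between the other two groups). Step 2a re-tests samples
#' routed to the asthma side with a panel separating asthma from
#' non-asthma/atopic; step 2b re-tests control-side samples with a panel
#' separating non-asthma/atopic from non-asthma/non-atopic. Panels may be
#' given or searched with [select_subset()] on the relevant training strata.
#'
#' @param data Feature table (`peak_matrix` or data frame / matrix).
#' @param labels Per-sample phenotype, one of [phenotype_levels].
#' @param panels Optional list with elements `step1`, `step2a`, `step2b`, each
#'   a vector of peak ids; any missing panel is searched.
#' @param k_max Maximum panel size for searched panels.
#' @param strategy Search strategy passed to [select_subset()].
#' @param n_per_group Optional size of the random per-group draw used to
#'   train steps 2a/2b (the study used all 8 atopic subjects plus 8 randomly
#'   drawn from each other group); `NULL` uses every available sample.
#' @param shrinkage LDA covariance shrinkage.
#' @param seed Seed for the step-2 random draw (only used with
#'   `n_per_group`).
#' @return An object of class `hierarchical_rule` with fitted
#'   `biomarker_panel`s `step1`, `step2a`, `step2b`.
#' @export
fit_hierarchical <- function(data, labels, panels = NULL, k_max = 5,
                             strategy = c("auto", "exhaustive", "greedy"),
                             n_per_group = NULL, shrinkage = 0.1, seed = NULL) {
  strategy <- match.arg(strategy)
  X <- feature_matrix(data)
  labels <- as.character(labels)
  if (!all(labels %in% phenotype_levels)) {
    abort_invalid(paste0("labels must be one of: ",
                         paste(phenotype_levels, collapse = ", ")))
  }
  if (length(labels) != nrow(X)) {
    abort_invalid("`labels` must have one entry per sample.")
  }
  if (!is.null(seed)) set.seed(seed)
  take <- function(idx) {
    if (is.null(n_per_group) || length(idx) <= n_per_group) idx
    else sort(sample(idx, n_per_group))
  }
  i_asthma <- which(labels == "asthma")
  i_atopic <- which(labels == "non-asthma/atopic")
  i_control <- which(labels == "non-asthma/non-atopic")
  if (!length(i_asthma) || !length(i_atopic) || !length(i_control)) {
    abort_invalid("all three phenotype groups must be present for fitting.")
  }
  fit_step <- function(rows, contrast, panel) {
    sub <- X[rows, , drop = FALSE]
    lab <- factor(labels[rows], levels = contrast)
    if (!is.null(panel)) {
      model <- fit_lda(sub, lab, subset = as.character(panel),
                       shrinkage = shrinkage)
      Zp <- standardize_cols(resolve_subset(sub, as.character(panel)))
      r <- loo_core(Zp, as.integer(lab) - 1L, shrinkage)
      structure(list(peak_ids = as.character(panel), cv_accuracy = r$accuracy,
                     cv_margin = r$margin,
                     boundary_distance = boundary_distance(model, sub, lab),
                     model = model,
                     comparison = paste(contrast, collapse = " vs "),
                     strategy = "fixed", k_max = length(panel)),
                class = "biomarker_panel")
    } else {
      select_subset(sub, lab, k_max = k_max, strategy = strategy,
                    shrinkage = shrinkage,
                    comparison = paste(contrast, collapse = " vs "))
    }
  }
  step1 <- fit_step(c(i_asthma, i_control),
                    c("non-asthma/non-atopic", "asthma"), panels$step1)
  step2a <- fit_step(c(take(i_asthma), i_atopic),
                     c("non-asthma/atopic", "asthma"), panels$step2a)
  step2b <- fit_step(c(i_atopic, take(i_control)),
                     c("non-asthma/non-atopic", "non-asthma/atopic"),
                     panels$step2b)
  structure(list(step1 = step1, step2a = step2a, step2b = step2b),
            class = "hierarchical_rule")
}

#' @export
print.hierarchical_rule <- function(x, ...) {
  cat("Two-step hierarchical phenotype rule\n")
  for (s in c("step1", "step2a", "step2b")) {
    cat(sprintf("  %-6s %-45s peaks {%s}  LOO %.3f\n", s, x[[s]]$comparison,
                paste(x[[s]]$peak_ids, collapse = ","), x[[s]]$cv_accuracy))
  }
  invisible(x)
}

#' @method glance hierarchical_rule
#' @export
glance.hierarchical_rule <- function(x, ...) {
  dplyr::bind_rows(lapply(x[c("step1", "step2a", "step2b")], glance),
                   .id = "step")
}

#' Classify samples with the two-step hierarchical rule
#'
#' Step 1 assigns each sample to the asthma or control side. Asthma-side
#' samples are re-tested by step 2a and may be relabelled non-asthma/atopic;
#' control-side samples are re-tested by step 2b likewise. Exactly one of the
#' three phenotype labels is returned per sample. Peaks referenced by a panel
#' but absent from `data` contribute area 0.
#'
#' @param data Feature table covering the rule's peaks (missing peak columns
#'   are zero-filled).
#' @param rule A fitted `hierarchical_rule`.
#' @return A tibble `sample_id`, `step1_label`, `final_label`.
#' @export
classify_two_step <- function(data, rule) {
  if (!inherits(rule, "hierarchical_rule")) {
    abort(message = "`rule` must be a fitted hierarchical_rule.",
          class = "breathvoc_state")
  }
  X <- feature_matrix(data)
  needed <- unique(c(rule$step1$peak_ids, rule$step2a$peak_ids,
                     rule$step2b$peak_ids))
  miss <- setdiff(needed, colnames(X))
  if (length(miss)) {
    X <- cbind(X, matrix(0, nrow(X), length(miss),
                         dimnames = list(NULL, miss)))
  }
  s1 <- predict(rule$step1$model, X)
  asthma_side <- s1 == "asthma"
  final <- character(nrow(X))
  if (any(asthma_side)) {
    final[asthma_side] <- predict(rule$step2a$model,
                                  X[asthma_side, , drop = FALSE])
  }
  if (any(!asthma_side)) {
    final[!asthma_side] <- predict(rule$step2b$model,
                                   X[!asthma_side, , drop = FALSE])
  }
  tibble(sample_id = rownames(X) %||% paste0("sample_", seq_len(nrow(X))),
         step1_label = s1, final_label = final)
}

#' Biomarker panel and projection for an asthma subgroup comparison
#'
#' Within the asthma stratum, derives the requested dichotomy from the
#' metadata (ICS treatment, obesity at BMI >= 30, blood eosinophils at
#' 0.3 x 10^9/L, or acute upper respiratory illness vs baseline), searches a
#' discriminatory panel with [select_subset()], and projects the stratum onto
#' the panel's PC plane with the LDA boundary.
#'
#' @param data Feature table with a `sample_id` column or rownames matching
#'   the metadata.
#' @param metadata Subject metadata ([subject_metadata()] is applied, so flags
#'   are rederived from raw BMI / eosinophil values).
#' @param comparison One of `"ics"`, `"obesity"`, `"eos"`, `"uri"`.
#' @param k_max,strategy,shrinkage Passed to [select_subset()].
#' @return A list of class `subgroup_result`: `panel` (a `biomarker_panel`),
#'   `projection` (a `voc_projection`), `comparison`, and the `samples`
#'   tibble with the derived flag.
#' @export
subgroup_panels <- function(data, metadata,
                            comparison = c("ics", "obesity", "eos", "uri"),
                            k_max = 5, strategy = c("auto", "exhaustive", "greedy"),
                            shrinkage = 0.1) {
  comparison <- match.arg(comparison)
  strategy <- match.arg(strategy)
  md <- subject_metadata(metadata)
  if (!"asthma" %in% names(md)) abort_invalid("metadata needs an `asthma` column.")
  md <- md[md$asthma %in% TRUE, ]
  flag <- switch(comparison,
    ics = md$ics_treatment,
    obesity = md$obese,
    eos = md$eos_high,
    uri = md$uri_state == "ill"
  )
  if (is.null(flag)) {
    abort_invalid(sprintf("metadata lacks the columns needed for '%s'.", comparison))
  }
  keep <- !is.na(flag)
  md <- md[keep, ]
  flag <- flag[keep]
  if (!any(flag) || all(flag)) {
    abort_invalid("both subgroup classes must be non-empty among asthma samples.")
  }
  X <- feature_matrix(data)
  rows <- match(md$sample_id, rownames(X))
  if (anyNA(rows)) abort_invalid("metadata sample_ids missing from `data`.")
  X <- X[rows, , drop = FALSE]
  lab <- factor(ifelse(flag, "positive", "negative"),
                levels = c("negative", "positive"))
  panel <- select_subset(X, lab, k_max = k_max, strategy = strategy,
                         shrinkage = shrinkage, comparison = comparison)
  projection <- if (length(panel$peak_ids) >= 2) {
    pca_project(X, panel = panel$peak_ids, model = panel$model)
  } else NULL
  md$flag <- flag
  structure(list(panel = panel, projection = projection,
                 comparison = comparison, samples = md),
            class = "subgroup_result")
}

#' Longitudinal trajectory of repeated samples in the PC plane
#'
#' Orders a subject's repeated visits in an existing projection and reports,
#' between consecutive visits, whether the path crosses the comparison's
#' decision boundary (visits on opposite sides).
#'
#' @param projection A `voc_projection` with a boundary.
#' @param data Feature table holding the subject's repeated samples.
#' @param visits A data frame with `sample_id` and `visit` (orderable) for one
#'   subject, or a vector of visit indices matching the rows of `data`.
#' @return A tibble ordered by visit: `sample_id`, `visit`, `PC1`, `PC2`,
#'   `side`, and `crossed` (`NA` for the first visit, then `TRUE` when the
#'   side changed from the previous visit).
#' @export
longitudinal_trajectory <- function(projection, data, visits) {
  sc <- project_samples(projection, data)
  if (is.data.frame(visits)) {
    sc <- dplyr::inner_join(sc, as_tibble(visits), by = "sample_id")
  } else {
    sc$visit <- visits
  }
  if (nrow(sc) < 2) abort_invalid("a trajectory needs at least two visits.")
  sc <- arrange(sc, .data$visit)
  sc$side <- boundary_side(projection, sc)
  sc$crossed <- c(NA, sc$side[-1] != sc$side[-nrow(sc)])
  sc
}
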