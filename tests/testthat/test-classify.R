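# PCA projection ---------------------------------------------------------------

test_that("collinear data put all variance on PC1", {
  t0 <- seq(-1, 1, length.out = 12)
  x <- cbind(t0, 2 * t0, -t0)
  colnames(x) <- as.character(1:3)
  pr <- pca_project(x)
  expect_equal(pr$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(pr$var_explained[-1], rep(0, 2), tolerance = 1e-12)
})

test_that("all principal components reconstruct the standardized input", {
  set.seed(17)
  x <- matrix(rnorm(15 * 4), 15, dimnames = list(NULL, 1:4))
  pr <- pca_project(x)
  z <- scale(x, center = pr$center, scale = pr$scale)
  scores_full <- z %*% pr$loadings
  expect_equal(scores_full %*% t(pr$loadings), z,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(diff(pr$var_explained) <= 1e-12))
  expect_equal(sum(pr$var_explained), 1, tolerance = 1e-12)
  expect_equal(colMeans(as.matrix(pr$scores[, c("PC1", "PC2")])), c(PC1 = 0, PC2 = 0),
               tolerance = 1e-10)
})

test_that("an isotropic cloud splits variance evenly over PC1 and PC2", {
  set.seed(23)
  x <- matrix(rnorm(1000 * 2), 1000, dimnames = list(NULL, 1:2))
  pr <- pca_project(x)
  expect_lt(pr$var_explained[1] / pr$var_explained[2], 1.1)
})

test_that("the projection is deterministic and sign-fixed", {
  set.seed(3)
  x <- matrix(rnorm(30 * 3), 30, dimnames = list(NULL, 1:3))
  p1 <- pca_project(x)
  p2 <- pca_project(x)
  expect_identical(p1$scores, p2$scores)
  for (j in seq_len(ncol(p1$loadings))) {
    v <- p1$loadings[, j]
    expect_gt(v[which.max(abs(v))], 0)
  }
  expect_error(pca_project(x[, 1, drop = FALSE]), class = "breathvoc_invalid")
  expect_error(pca_project(x[1:2, ]), class = "breathvoc_invalid")
})

test_that("the mapped boundary line separates the same samples as the LDA", {
  set.seed(41)
  x <- rbind(matrix(rnorm(60, 0), ncol = 3), matrix(rnorm(60, 2), ncol = 3))
  colnames(x) <- as.character(1:3)
  lab <- rep(c("ctrl", "case"), each = 20)
  fit <- fit_lda(x, lab)
  pr <- pca_project(x, model = fit)
  side <- boundary_side(pr)
  lda_side <- predict(fit, x)
  # the PC1-PC2 plane holds nearly all variance here, so the mapped line
  # must agree with the full-space rule for nearly every sample
  agreement <- mean((side == "positive") == (lda_side == fit$levels[2]))
  expect_gte(agreement, 0.95)
})

# subject metadata --------------------------------------------------------------

test_that("clinical flags are rederived exactly at their thresholds", {
  md <- subject_metadata(data.frame(
    sample_id = c("a", "b", "c", "d"),
    bmi = c(30, 29.9, 35, 18),
    blood_eos = c(0.3, 0.29, 1.2, 0.05),
    obese = c(FALSE, TRUE, NA, NA),      # deliberately wrong: must be ignored
    eos_high = c(FALSE, TRUE, NA, NA)
  ))
  expect_identical(md$obese, c(TRUE, FALSE, TRUE, FALSE))
  expect_identical(md$eos_high, c(TRUE, FALSE, TRUE, FALSE))
})

test_that("derived flags always match recomputation from the raw values", {
  set.seed(7)
  md <- subject_metadata(data.frame(
    sample_id = sprintf("s%02d", 1:50),
    bmi = runif(50, 15, 45),
    blood_eos = runif(50, 0, 1)
  ))
  expect_identical(md$obese, md$bmi >= 30)
  expect_identical(md$eos_high, md$blood_eos >= 0.3)
  expect_error(subject_metadata(data.frame(sample_id = "x", uri_state = "sick")),
               class = "breathvoc_invalid")
})

# two-step classification --------------------------------------------------------

test_that("the two-step rule labels centroid samples as constructed", {
  d <- three_group_design(n_per_group = 12, seed = 31)
  td <- truth_data(d)
  rule <- fit_hierarchical(td$matrix, td$labels, k_max = 4)
  X <- feature_matrix(td$matrix)
  centroid <- function(g) {
    cm <- colMeans(X[td$labels == g, , drop = FALSE])
    matrix(cm, 1, dimnames = list("c", names(cm)))
  }
  expect_identical(classify_two_step(centroid("asthma"), rule)$final_label,
                   "asthma")
  expect_identical(
    classify_two_step(centroid("non-asthma/non-atopic"), rule)$final_label,
    "non-asthma/non-atopic")
  expect_identical(
    classify_two_step(centroid("non-asthma/atopic"), rule)$final_label,
    "non-asthma/atopic")
})

test_that("every sample gets exactly one of the three labels", {
  d <- three_group_design(n_per_group = 10, seed = 5)
  td <- truth_data(d)
  rule <- fit_hierarchical(td$matrix, td$labels, k_max = 3)
  out <- classify_two_step(td$matrix, rule)
  expect_equal(nrow(out), 30)
  expect_true(all(out$final_label %in% phenotype_levels))
  expect_true(all(out$step1_label %in%
                    c("asthma", "non-asthma/non-atopic")))
  expect_error(classify_two_step(td$matrix, structure(list(), class = "x")),
               class = "breathvoc_state")
})

test_that("atopic samples are the ones step 1 misroutes most", {
  d <- three_group_design(n_per_group = 15, seed = 8)
  td <- truth_data(d)
  rule <- fit_hierarchical(td$matrix, td$labels, k_max = 4)
  out <- classify_two_step(td$matrix, rule)
  # step 1 alone can never name atopy, and for the two trained groups it
  # should be mostly right; atopic samples split across both sides
  s1_err <- function(g, correct) {
    mean(out$step1_label[td$labels == g] != correct)
  }
  atopic_err <- 1  # atopic can never be right at step 1
  expect_gt(atopic_err, s1_err("asthma", "asthma"))
  expect_gt(atopic_err, s1_err("non-asthma/non-atopic", "non-asthma/non-atopic"))
  # the full rule recovers a majority of atopic samples
  rec <- mean(out$final_label[td$labels == "non-asthma/atopic"] ==
                "non-asthma/atopic")
  expect_gte(rec, 0.6)
})

test_that("two-step held-out accuracy beats step-1-only routing", {
  train <- truth_data(three_group_design(n_per_group = 15, seed = 12))
  test <- truth_data(three_group_design(n_per_group = 15, seed = 93))
  rule <- fit_hierarchical(train$matrix, train$labels, k_max = 4)
  out <- classify_two_step(test$matrix, rule)
  acc_two_step <- mean(out$final_label == test$labels)
  acc_step1 <- mean(out$step1_label == test$labels)
  expect_gt(acc_two_step, acc_step1)
  expect_gte(acc_two_step, 0.8)
})

# subgroup panels ----------------------------------------------------------------

test_that("a planted ICS-effect peak is recovered within the asthma stratum", {
  lib <- peak_library(n_peaks = 20, seed = 2)
  lib <- set_marker_effects(lib, 11, c(ics = 3))
  d <- cohort_design(c(ics = 10, no_ics = 10), peaks = lib, seed = 77)
  coh <- simulate_cohort(d, render = FALSE)
  tm <- truth_matrix(coh)
  md <- subject_metadata(data.frame(
    sample_id = tm$sample_id,
    asthma = TRUE,
    ics_treatment = coh$samples$group[match(tm$sample_id,
                                            coh$samples$sample_id)] == "ics"
  ))
  res <- subgroup_panels(tm, md, comparison = "ics", k_max = 3)
  expect_true("11" %in% res$panel$peak_ids)
  expect_gte(res$panel$cv_accuracy, 0.9)
  expect_s3_class(res$projection, "voc_projection")
})

test_that("subgroup comparisons honor the clinical thresholds edge-exactly", {
  lib <- peak_library(n_peaks = 6, seed = 3)
  d <- cohort_design(c(a = 8), peaks = lib, seed = 4)
  tm <- truth_matrix(simulate_cohort(d, render = FALSE))
  md_base <- data.frame(sample_id = tm$sample_id, asthma = TRUE)
  md <- cbind(md_base, bmi = c(30, 30, 30, 30, 29.9, 29.9, 29.9, 29.9))
  res <- subgroup_panels(tm, md, comparison = "obesity", k_max = 1)
  expect_equal(sum(res$samples$flag), 4)
  md2 <- cbind(md_base, blood_eos = c(rep(0.3, 4), rep(0.29, 4)))
  res2 <- subgroup_panels(tm, md2, comparison = "eos", k_max = 1)
  expect_equal(sum(res2$samples$flag), 4)
  # one-sided strata are invalid
  md3 <- cbind(md_base, bmi = rep(40, 8))
  expect_error(subgroup_panels(tm, md3, comparison = "obesity"),
               class = "breathvoc_invalid")
})

# longitudinal trajectories -------------------------------------------------------

test_that("trajectories report boundary crossings between visits", {
  set.seed(19)
  x <- rbind(matrix(rnorm(45, 0), ncol = 3), matrix(rnorm(45, 3), ncol = 3))
  colnames(x) <- as.character(1:3)
  lab <- rep(c("baseline", "ill"), each = 15)
  fit <- fit_lda(x, lab)
  pr <- pca_project(x, model = fit)
  # visit 1 at the baseline centroid, visit 2 at the ill centroid
  v <- rbind(colMeans(x[1:15, ]), colMeans(x[16:30, ]))
  rownames(v) <- c("v1", "v2")
  traj <- longitudinal_trajectory(pr, v, visits = c(1, 2))
  expect_identical(traj$crossed, c(NA, TRUE))
  expect_false(traj$side[1] == traj$side[2])
  # identical repeated sample never crosses
  v2 <- v[c(1, 1), ]
  rownames(v2) <- c("v1", "v2")
  traj2 <- longitudinal_trajectory(pr, v2, visits = c(1, 2))
  expect_identical(traj2$crossed, c(NA, FALSE))
  expect_equal(traj2$PC1[1], traj2$PC1[2])
  expect_error(longitudinal_trajectory(pr, v[1, , drop = FALSE], visits = 1),
               class = "breathvoc_invalid")
})

test_that("a planted illness shift moves trajectories toward the ill side", {
  moved <- vapply(1:25, function(seed) {
    lib <- peak_library(n_peaks = 12, seed = 2)
    lib <- set_marker_effects(lib, c(6, 9), c(ill = 2.5))
    d <- cohort_design(c(baseline = 10, ill = 10), peaks = lib, seed = seed)
    coh <- simulate_cohort(d, render = FALSE)
    tm <- truth_matrix(coh)
    lab <- coh$samples$group[match(tm$sample_id, coh$samples$sample_id)]
    fit <- fit_lda(tm, lab, subset = c("6", "9"))
    pr <- pca_project(tm, panel = c("6", "9"), model = fit)
    X <- feature_matrix(tm)
    v <- rbind(colMeans(X[lab == "baseline", ]), colMeans(X[lab == "ill", ]))
    rownames(v) <- c("v1", "v2")
    traj <- longitudinal_trajectory(pr, v, visits = c(1, 2))
    ill_positive <- fit$levels[2] == "ill"
    d1 <- pr$boundary$a1 * traj$PC1 + pr$boundary$a2 * traj$PC2 + pr$boundary$b
    if (ill_positive) d1[2] > d1[1] else d1[2] < d1[1]
  }, logical(1))
  expect_gte(mean(moved), 0.9)
})
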