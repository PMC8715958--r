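make_volume_set <- function(n_per, d = c(8, 8, 8), effect_mask = NULL,
                            effect = 0, noise = 0.1, seed = 1) {
  set.seed(seed)
  mask <- array(TRUE, d)
  mk <- function(shift) {
    a <- array(1 + rnorm(prod(d), 0, noise), d)
    if (!is.null(effect_mask)) a[effect_mask] <- a[effect_mask] - shift
    brain_volume(a, mask = mask)
  }
  list(volumes = c(replicate(n_per, mk(effect), simplify = FALSE),
                   replicate(n_per, mk(0), simplify = FALSE)),
       group = rep(c(1, 0), each = n_per))
}

test_that("voxel t-map without covariates equals the pooled two-sample t", {
  vs <- make_volume_set(10, noise = 0.2, seed = 40)
  map <- glm_tmap(vs$volumes, vs$group)
  expect_equal(map$df, 20 - 2)
  Y <- sapply(vs$volumes, function(v) v$data[1:20])
  for (vox in 1:20) {
    tt <- t.test(Y[vox, vs$group == 1], Y[vox, vs$group == 0], var.equal = TRUE)
    expect_equal(map$t[vox], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected with the offending column", {
  vs <- make_volume_set(5, seed = 41)
  expect_error(glm_tmap(vs$volumes, rep(1, 10)), class = "petriage_design_error")
  cov_bad <- data.frame(age = rep(3, 10))
  expect_error(glm_tmap(vs$volumes, vs$group, cov_bad),
               class = "petriage_design_error", regexp = "age")
})

test_that("covariate adjustment matches lm per voxel", {
  vs <- make_volume_set(8, seed = 42)
  cov <- data.frame(age = rnorm(16, 70, 5), sex = sample(c("M", "F"), 16, TRUE))
  map <- glm_tmap(vs$volumes, vs$group, cov)
  v1 <- sapply(vs$volumes, function(v) v$data[7])
  fit <- summary(stats::lm(v1 ~ vs$group + cov$age + I(as.integer(factor(cov$sex)) - 1)))
  expect_equal(map$t[7], fit$coefficients[2, 3], tolerance = 1e-8)
  expect_equal(map$df, 16 - 4)
})

test_that("FWE threshold is alpha / V and FDR follows the step-up rule", {
  vs <- make_volume_set(6, seed = 43)
  map <- glm_tmap(vs$volumes, vs$group)
  map <- threshold_map(map, "fwe", 0.05)
  expect_equal(map$sig_info$fwe$voxel_threshold, 0.05 / map$V)
  # hand example: p = {.01,.02,.03,.04}, m = 4, alpha = .05 -> all rejected
  p <- c(0.01, 0.02, 0.03, 0.04)
  expect_true(all(stats::p.adjust(p, "BH") < 0.05))
  # brute-force step-up oracle vs p.adjust on random vectors
  set.seed(44)
  for (i in 1:200) {
    m <- sample(3:60, 1)
    p <- round(runif(m), sample(1:4, 1))
    bh_reject <- stats::p.adjust(p, "BH") <= 0.05
    ord <- order(p)
    ks <- which(p[ord] <= seq_len(m) * 0.05 / m)
    brute <- rep(FALSE, m)
    if (length(ks)) brute[ord[seq_len(max(ks))]] <- TRUE
    expect_equal(bh_reject, brute)
  }
  # all p = 1: both masks empty
  vs0 <- make_volume_set(6, noise = 1e-6, seed = 45)
  map0 <- glm_tmap(vs0$volumes, vs0$group)
  map0$t[] <- 0
  map0 <- threshold_map(threshold_map(map0, "fwe"), "fdr")
  expect_equal(sum(map0$sig$fwe), 0)
  expect_equal(sum(map0$sig$fdr), 0)
  expect_error(threshold_map(map0, "fwe", alpha = 1.5),
               class = "petriage_parameter_error")
})

test_that("cluster filtering applies strict extent and 18-connectivity", {
  d <- c(10, 10, 10)
  m <- array(FALSE, d)
  m[1:5, 1, 1] <- TRUE  # 5-voxel line: removed under strict > 5
  out <- cluster_filter(m, min_extent = 5)
  expect_equal(sum(out$mask), 0)
  expect_equal(out$clusters$size, 5)
  expect_false(out$clusters$kept)
  m[1:6, 5, 5] <- TRUE  # 6-voxel line: kept
  out <- cluster_filter(m, min_extent = 5)
  expect_equal(sum(out$mask), 6)
  # diagonal face-touching voxels: one cluster under 18, two under 6
  m2 <- array(FALSE, d)
  m2[3, 3, 3] <- TRUE; m2[4, 4, 3] <- TRUE
  expect_equal(nrow(cluster_filter(m2, 0, connectivity = 18)$clusters), 1)
  expect_equal(nrow(cluster_filter(m2, 0, connectivity = 6)$clusters), 2)
  # corner-touching: separate under 18, joined under 26
  m3 <- array(FALSE, d)
  m3[3, 3, 3] <- TRUE; m3[4, 4, 4] <- TRUE
  expect_equal(nrow(cluster_filter(m3, 0, connectivity = 18)$clusters), 2)
  expect_equal(nrow(cluster_filter(m3, 0, connectivity = 26)$clusters), 1)
  # empty mask allowed
  expect_equal(nrow(cluster_filter(array(FALSE, d))$clusters), 0)
})

test_that("ROI comparison detects the injected effect and not the rest", {
  atlas <- fixture_atlas()
  cfg <- generator_config(seed = 46)
  prec <- atlas$labels == atlas$names[["precuneus"]]
  set.seed(46)
  mk <- function(effect) {
    a <- ifelse(atlas$brain_mask, 1.2, 0)
    a[prec] <- a[prec] * (1 - effect)
    a <- a + array(rnorm(length(a), 0, 0.05), dim(a))
    brain_volume(array(a, dim(atlas$labels)), mask = atlas$brain_mask)
  }
  vols <- c(replicate(60, mk(0.15), simplify = FALSE),
            replicate(60, mk(0), simplify = FALSE))
  group <- rep(c(1, 0), each = 60)
  res <- roi_compare(vols, atlas, group)
  expect_lt(res$p_fwe[res$roi == "precuneus"], 0.001)
  others <- res$p_fwe[res$roi != "precuneus"]
  expect_true(all(others > 0.05))
  # all-equal volumes give t = 0 everywhere
  flat <- replicate(10, brain_volume(array(1, dim(atlas$labels)),
                                     mask = atlas$brain_mask), simplify = FALSE)
  res0 <- roi_compare(flat, atlas, rep(c(1, 0), each = 5))
  expect_true(all(res0$t == 0))
})

test_that("GDS battery: corrected threshold, worked 2x2 example, factor links", {
  cohort <- fixture_cohort()
  cohort$diagnosis <- ifelse(cohort$triage_label == "uncertain",
                             cohort$true_state, "none")
  res <- gds_itemwise(cohort, "certainty")
  expect_equal(attr(res, "threshold"), 0.05 / 16)
  expect_equal(signif(attr(res, "threshold"), 2), 0.0031)
  expect_equal(nrow(res), 16)
  # no-association table: chi-squared 0, p = 1
  flat <- suppressWarnings(stats::chisq.test(matrix(10, 2, 2), correct = FALSE))
  expect_equal(unname(flat$statistic), 0)
  expect_equal(flat$p.value, 1)
  # closed-form 2x2: [[30,10],[10,30]] -> X^2 = 20, p ~ 7.7e-6
  tab <- matrix(c(30, 10, 10, 30), 2, 2)
  ct <- stats::chisq.test(tab, correct = FALSE)
  expect_equal(unname(ct$statistic), 20)
  expect_equal(ct$p.value, 7.7e-6, tolerance = 0.01)
})

test_that("GDS memory and energy items associate with the designed factors", {
  cfg <- generator_config(n_samples = 1500, seed = 47)
  cohort <- triage_cohort(generate_cohort(cfg))
  cohort$diagnosis <- ifelse(cohort$triage_label == "uncertain",
                             cohort$true_state, "none")  # oracle diagnoses
  imp <- gds_itemwise(cohort, "impairment")
  cert <- gds_itemwise(cohort, "certainty")
  expect_true(imp$significant[imp$test == "gds_memory"])
  expect_true(cert$significant[cert$test == "gds_energy"])
  expect_false(imp$significant[imp$test == "gds_energy"])
})

test_that("subsampled ANOVA is balanced, seeded and detects injected effects", {
  cfg <- generator_config(n_samples = 600, seed = 48)
  cohort <- triage_cohort(generate_cohort(cfg))
  cohort$diagnosis <- ifelse(cohort$triage_label == "uncertain",
                             cohort$true_state, "none")
  cohort <- final_labels(cohort)
  # inject a pure certainty effect on the response
  cohort$gds_shifted <- cohort$gds_total + 2 * (cohort$certainty == "certain") +
    rnorm(nrow(cohort), 0, 0.5)
  res <- anova_subsampled(cohort, "gds_shifted", repeats = 50, seed = 5)
  expect_lt(res$mean_p["certainty"], 0.001)
  expect_gt(res$mean_p["impairment"], 0.01)
  expect_equal(res$subsample_size,
               min(table(cohort$certainty, cohort$impairment)))
  res2 <- anova_subsampled(cohort, "gds_shifted", repeats = 50, seed = 5)
  expect_identical(res$p_values, res2$p_values)
  # degenerate zero-variance response reports absent p-values
  cohort$flat <- 1
  res0 <- anova_subsampled(cohort, "flat", repeats = 3, seed = 1)
  expect_true(all(is.na(res0$p_values$p_certainty)))
  # missing cell errors
  bad <- cohort[cohort$certainty == "certain", ]
  expect_error(anova_subsampled(bad, "gds_total"), class = "petriage_grouping_error")
})
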