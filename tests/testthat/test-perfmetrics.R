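test_that("classification metrics handle worked examples and edge cases", {
  m <- classification_metrics(tp = 292, fp = 9, tn = 324, fn = 20)
  expect_equal(round(m$accuracy, 2), 95.50)
  expect_equal(round(m$precision, 2), 97.01)
  expect_equal(round(m$sensitivity, 2), 93.59)
  expect_equal(round(m$specificity, 2), 97.30)
  expect_equal(round(m$f1, 2), 95.27)
  perfect <- classification_metrics(tp = 10, fp = 0, tn = 10, fn = 0)
  expect_true(all(unlist(perfect) == 100))
  # undefined ratios reported absent, not zero
  none_pos <- classification_metrics(tp = 0, fp = 0, tn = 5, fn = 5)
  expect_true(is.na(none_pos$precision))
  expect_equal(none_pos$accuracy, 50)
  expect_error(classification_metrics(tp = 0, fp = 0, tn = 0, fn = 0),
               class = "petriage_empty_input_error")
})

test_that("metric identities hold on random confusion counts", {
  set.seed(20)
  for (i in 1:50) {
    tp <- rpois(1, 30) + 1; fp <- rpois(1, 10); tn <- rpois(1, 30) + 1; fn <- rpois(1, 10)
    m <- classification_metrics(tp = tp, fp = fp, tn = tn, fn = fn)
    n <- tp + fp + tn + fn
    acc_id <- (m$sensitivity / 100 * (tp + fn) + m$specificity / 100 * (tn + fp)) / n
    expect_equal(m$accuracy / 100, acc_id, tolerance = 1e-12)
    expect_equal(m$f1 / 100, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
  }
})

test_that("AUC matches the brute-force pairwise oracle", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1.0)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  set.seed(21)
  for (i in 1:100) {
    n <- sample(4:50, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- round(rnorm(n), sample(0:2, 1))  # ties likely
    brute <- {
      pos <- s[y == 1]; neg <- s[y == 0]
      cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
      mean(cmp)
    }
    expect_equal(roc_auc(y, s), brute, tolerance = 1e-12)
  }
  expect_error(roc_auc(rep(1, 5), rnorm(5)), class = "petriage_class_error")
})

test_that("cross-validation folds partition samples at subject level", {
  set.seed(22)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    subjects <- sample(paste0("sub", seq_len(max(5, n %/% 2))), n, replace = TRUE)
    fold <- petriage:::.assign_folds(subjects, 5, seed = i)
    expect_length(fold, n)
    expect_true(all(fold %in% 1:5))
    # all samples of one subject share a fold
    expect_true(all(tapply(fold, subjects, function(f) length(unique(f))) == 1))
  }
  expect_error(petriage:::.assign_folds(c("a", "b"), 5, 1),
               class = "petriage_fold_error")
})

test_that("cross-validation harness tests each sample exactly once", {
  fx <- fixture_tiny_volumes()
  cv <- crossvalidate(fx$volumes, fx$labels, spec = tiny_spec(),
                      config = tiny_config(max_epochs = 6), k = 4, seed = 2)
  expect_equal(sort(cv$samples$id), sort(cv$fold_assignment$id))
  expect_equal(nrow(cv$samples), length(fx$labels))
  counts <- cv$pooled_counts
  expect_equal(counts$tp + counts$fp + counts$tn + counts$fn, length(fx$labels))
  expect_s3_class(tidy(cv), "tbl_df")
  expect_equal(nrow(tidy(cv)), 4)
  expect_equal(glance(cv)$n, length(fx$labels))
  # baseline classifiers run through the same harness
  cvb <- crossvalidate(lapply(fx$volumes, brain_volume), fx$labels,
                       spec = tiny_spec(), config = tiny_config(),
                       k = 4, seed = 2, classifier = "c_svm_linear")
  expect_equal(nrow(cvb$samples), length(fx$labels))
  expect_gt(cvb$pooled_metrics$accuracy, 60)
})

test_that("PCA embedding is exact on planar data", {
  set.seed(23)
  n <- 40
  basis <- qr.Q(qr(matrix(rnorm(20 * 2), 20, 2)))
  plane <- matrix(rnorm(n * 2), n, 2)
  x <- plane %*% t(basis)  # 2-D data embedded in 20 dimensions
  emb <- embed_2d(x, "pca")
  d_orig <- dist(plane)
  d_emb <- dist(cbind(emb$dim1, emb$dim2))
  expect_equal(as.numeric(d_emb), as.numeric(d_orig), tolerance = 1e-8)
  # explained variance matches an independent eigen-decomposition
  ev <- attr(emb, "explained_variance")
  eig <- sort(eigen(cov(x), symmetric = TRUE)$values, decreasing = TRUE)[1:2]
  expect_equal(unname(ev), eig, tolerance = 1e-8)
  expect_error(embed_2d(x[1:2, ]), class = "petriage_input_error")
})

test_that("t-SNE is seed-reproducible and separates distinct clusters", {
  set.seed(24)
  x <- rbind(matrix(rnorm(25 * 5, mean = 0), ncol = 5),
             matrix(rnorm(25 * 5, mean = 8), ncol = 5))
  e1 <- embed_2d(x, "tsne", seed = 3, perplexity = 10)
  e2 <- embed_2d(x, "tsne", seed = 3, perplexity = 10)
  expect_identical(e1, e2)
  lab <- rep(1:2, each = 25)
  centroid_gap <- sqrt(sum((colMeans(cbind(e1$dim1, e1$dim2)[lab == 1, ]) -
                              colMeans(cbind(e1$dim1, e1$dim2)[lab == 2, ]))^2))
  within <- mean(c(dist(cbind(e1$dim1, e1$dim2)[lab == 1, ])))
  expect_gt(centroid_gap, within)
})
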