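#' Confusion counts with the impaired class positive
#'
#' @param truth,pred Binary vectors (1/`"impaired"` = positive).
#' @return Object of class `confusion_counts`: list `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, pred) {
  truth <- .coerce_labels(truth)
  pred <- .coerce_labels(pred)
  structure(
    list(tp = sum(truth == 1 & pred == 1), fp = sum(truth == 0 & pred == 1),
         tn = sum(truth == 0 & pred == 0), fn = sum(truth == 1 & pred == 0)),
    class = "confusion_counts"
  )
}

#' Classification metrics from confusion counts
#'
#' Accuracy, precision, sensitivity (recall of the impaired class),
#' specificity and F1, reported as percentages. A ratio with a zero
#' denominator is reported as `NA` (absent), never as 0.
#'
#' @param counts A [confusion_counts()] object, or `NULL` when the four
#'   counts are given individually.
#' @param tp,fp,tn,fn Counts when given individually.
#' @return One-row tibble of percentages.
#' @examples
#' classification_metrics(tp = 292, fp = 9, tn = 324, fn = 20)
#' @export
classification_metrics <- function(counts = NULL, tp = NULL, fp = NULL,
                                   tn = NULL, fn = NULL) {
  if (!inherits(counts, "confusion_counts")) {
    counts <- structure(list(tp = tp %||% counts, fp = fp, tn = tn, fn = fn),
                        class = "confusion_counts")
  }
  with(counts, {
    n <- tp + fp + tn + fn
    if (n == 0) stop_petriage("no observations.", "petriage_empty_input_error")
    ratio <- function(num, den) if (den > 0) num / den else NA_real_
    prec <- ratio(tp, tp + fp)
    sens <- ratio(tp, tp + fn)
    f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
      2 * prec * sens / (prec + sens)
    } else {
      NA_real_
    }
    tibble::tibble(
      accuracy = 100 * (tp + tn) / n,
      precision = 100 * prec,
      sensitivity = 100 * sens,
      specificity = 100 * ratio(tn, tn + fp),
      f1 = 100 * f1
    )
  })
}

#' Area under the ROC curve
#'
#' Computed by the rank (concordance) formula:
#' (concordant pairs + half the tied pairs) / (n1 * n0), equivalent to
#' trapezoidal integration of the ROC curve.
#'
#' @param labels Binary labels (1/`"impaired"` = positive).
#' @param scores Real-valued decision scores.
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8))
#' @export
roc_auc <- function(labels, scores) {
  y <- .coerce_labels(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) {
    stop_petriage("both classes must be present to compute AUC.",
                  "petriage_class_error")
  }
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Subject-level fold assignment: all samples of a subject share a fold.
.assign_folds <- function(subjects, k, seed) {
  us <- unique(subjects)
  if (length(us) < k) {
    stop_petriage(sprintf("%d subjects cannot fill %d folds.", length(us), k),
                  "petriage_fold_error")
  }
  shuffled <- with_seed(seed, sample(us))
  fold_of <- stats::setNames(rep(seq_len(k), length.out = length(us)), shuffled)
  unname(fold_of[as.character(subjects)])
}

#' Fivefold cross-validation of the classifier on certain cases
#'
#' Samples are split into `k` subject-level folds (all volumes of a subject
#' share a fold). In rotation *i*, fold *i* is the test set, fold
#' *i + 1 (mod k)* the monitored validation set and the remaining folds the
#' training set — a 60/20/20 split at `k = 5`. Per-fold confusion counts
#' and metrics are reported alongside pooled counts and the pooled AUC.
#'
#' @param volumes List of volumes (certain cases only).
#' @param labels Binary labels aligned with `volumes`.
#' @param subjects Subject identifier per sample (defaults to one subject
#'   per sample).
#' @param spec A [network_spec()] (for `classifier = "cnn"`).
#' @param config A [train_config()].
#' @param k Number of folds.
#' @param seed Fold-assignment seed.
#' @param classifier `"cnn"` or a [fit_baseline()] kind.
#' @return Object of class `cv_result`.
#' @export
crossvalidate <- function(volumes, labels, subjects = NULL,
                          spec = network_spec(input_edge = 32),
                          config = train_config(), k = 5L, seed = 1L,
                          classifier = "cnn") {
  y <- .coerce_labels(labels)
  n <- length(y)
  if (n < k) stop_petriage("fewer samples than folds.", "petriage_fold_error")
  subjects <- subjects %||% seq_len(n)
  fold <- .assign_folds(subjects, k, seed)
  ids <- names(volumes) %||% sprintf("V%04d", seq_len(n))

  use_cnn <- identical(classifier, "cnn")
  feats <- if (!use_cnn) baseline_features(volumes) else NULL

  rows <- vector("list", k)
  fold_metrics <- vector("list", k)
  for (i in seq_len(k)) {
    test <- fold == i
    val <- fold == (i %% k) + 1L
    train <- !test & !val
    if (use_cnn) {
      model <- build_network(spec, seed = config$seed)
      model <- nn_train(model, volumes[train], y[train], config,
                        validation = list(volumes = volumes[val], labels = y[val]))
      prob <- nn_predict(model, volumes[test])
      pred <- as.integer(prob >= config$decision_threshold)
    } else {
      bl <- fit_baseline(classifier, feats[train, , drop = FALSE], y[train],
                         seed = config$seed)
      prob <- predict(bl, feats[test, , drop = FALSE], type = "score")
      pred <- predict(bl, feats[test, , drop = FALSE], type = "class")
    }
    rows[[i]] <- tibble::tibble(
      id = ids[test], subject = subjects[test], fold = i,
      label = y[test], score = prob, pred = pred
    )
    cm <- confusion_counts(y[test], pred)
    fold_metrics[[i]] <- dplyr::bind_cols(tibble::tibble(fold = i),
                                          classification_metrics(cm),
                                          tibble::as_tibble(unclass(cm)))
  }
  samples <- dplyr::bind_rows(rows)
  pooled_counts <- confusion_counts(samples$label, samples$pred)
  structure(
    list(
      samples = samples,
      fold_metrics = dplyr::bind_rows(fold_metrics),
      pooled_counts = pooled_counts,
      pooled_metrics = classification_metrics(pooled_counts),
      pooled_auc = roc_auc(samples$label, samples$score),
      fold_assignment = tibble::tibble(id = ids, subject = subjects, fold = fold),
      classifier = classifier, k = k
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s, %d folds, pooled accuracy %.2f%%, AUC %.4f\n",
              x$classifier, x$k, x$pooled_metrics$accuracy, x$pooled_auc))
  invisible(x)
}

#' Two-dimensional embedding of network features
#'
#' `"pca"` projects onto the top two eigenvectors of the centred
#' covariance (deterministic up to sign); `"tsne"` runs a t-distributed
#' stochastic neighbour embedding, reproducible given `seed`.
#'
#' @param features Matrix, one row per sample (>= 3 rows).
#' @param method `"pca"` or `"tsne"`.
#' @param seed Seed for the stochastic embedding.
#' @param perplexity t-SNE perplexity (capped at `(n - 1) / 3`).
#' @return Tibble with columns `dim1`, `dim2` (class `petriage_embedding`),
#'   with the PCA explained variances in attribute `"explained_variance"`.
#' @export
embed_2d <- function(features, method = c("pca", "tsne"), seed = 1L,
                     perplexity = 30) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 3L) {
    stop_petriage("at least 3 feature vectors are required.", "petriage_input_error")
  }
  if (method == "pca") {
    pc <- stats::prcomp(features, center = TRUE, scale. = FALSE)
    out <- tibble::tibble(dim1 = pc$x[, 1], dim2 = pc$x[, 2])
    attr(out, "explained_variance") <- pc$sdev[1:2]^2
  } else {
    coords <- .tsne(features, seed = seed, perplexity = perplexity)
    out <- tibble::tibble(dim1 = coords[, 1], dim2 = coords[, 2])
  }
  class(out) <- c("petriage_embedding", class(out))
  attr(out, "method") <- method
  out
}
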