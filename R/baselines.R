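#' Baseline classifiers on masked-voxel features
#'
#' Comparator models operating on flattened voxel features: a three-layer
#' multilayer perceptron (`mlp3`, one hidden layer via \pkg{nnet}),
#' C-/nu-SVMs with linear or radial kernels (via \pkg{e1071}/libsvm),
#' ordinary linear regression on the 0/1 label (fitted value thresholded at
#' 0.5) and logistic regression. Every fit is deterministic given `seed`.
#'
#' @param kind One of `"mlp3"`, `"c_svm_linear"`, `"c_svm_rbf"`,
#'   `"nu_svm_linear"`, `"nu_svm_rbf"`, `"linear_reg"`, `"logistic_reg"`.
#' @param features Numeric matrix, one row per sample.
#' @param labels Binary labels (1/`"impaired"` = positive).
#' @param seed Seed (used by the stochastically initialised models).
#' @return Object of class `baseline_model`; use [predict.baseline_model()]
#'   for decision scores or class labels.
#' @export
fit_baseline <- function(kind, features, labels, seed = 0L) {
  kinds <- c("mlp3", "c_svm_linear", "c_svm_rbf", "nu_svm_linear",
             "nu_svm_rbf", "linear_reg", "logistic_reg")
  if (!is.character(kind) || length(kind) != 1L || !kind %in% kinds) {
    stop_petriage(sprintf("unknown baseline kind; expected one of %s.",
                          paste(kinds, collapse = ", ")),
                  "petriage_parameter_error")
  }
  features <- as.matrix(features)
  y <- .coerce_labels(labels)
  if (nrow(features) != length(y)) {
    stop_petriage("features and labels lengths differ.", "petriage_input_error")
  }

  fit <- with_seed(seed, switch(
    kind,
    mlp3 = nnet::nnet(features, y, size = 16, decay = 1e-4, maxit = 500,
                      entropy = TRUE, skip = TRUE, trace = FALSE, MaxNWts = 1e7),
    c_svm_linear = e1071::svm(features, factor(y, levels = c(0, 1)),
                              type = "C-classification", kernel = "linear",
                              scale = FALSE),
    c_svm_rbf = e1071::svm(features, factor(y, levels = c(0, 1)),
                           type = "C-classification", kernel = "radial",
                           scale = FALSE),
    nu_svm_linear = e1071::svm(features, factor(y, levels = c(0, 1)),
                               type = "nu-classification", kernel = "linear",
                               nu = 0.3, scale = FALSE),
    nu_svm_rbf = e1071::svm(features, factor(y, levels = c(0, 1)),
                            type = "nu-classification", kernel = "radial",
                            nu = 0.3, scale = FALSE),
    linear_reg = stats::lm.fit(cbind(1, features), y),
    logistic_reg = suppressWarnings(
      stats::glm.fit(cbind(1, features), y, family = stats::binomial())
    )
  ))
  structure(list(kind = kind, fit = fit, seed = seed),
            class = "baseline_model")
}

#' @rdname fit_baseline
#' @param object A `baseline_model`.
#' @param newdata Feature matrix to score.
#' @param type `"score"` for the real decision score (oriented so larger
#'   means more impaired), `"class"` for 0/1 labels.
#' @param ... Unused.
#' @export
predict.baseline_model <- function(object, newdata, type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  score <- switch(
    object$kind,
    mlp3 = as.numeric(stats::predict(object$fit, newdata)),
    linear_reg = {
      coefs <- object$fit$coefficients
      coefs[is.na(coefs)] <- 0
      as.numeric(cbind(1, newdata) %*% coefs)
    },
    logistic_reg = {
      coefs <- object$fit$coefficients
      coefs[is.na(coefs)] <- 0
      stats::plogis(as.numeric(cbind(1, newdata) %*% coefs))
    },
    { # SVM variants: signed decision value, oriented toward class "1"
      dv <- attr(stats::predict(object$fit, newdata, decision.values = TRUE),
                 "decision.values")
      s <- as.numeric(dv[, 1])
      if (grepl("^0/1$", colnames(dv)[1])) s <- -s
      s
    }
  )
  if (type == "score") return(score)
  # probability-scale scorers cut at 0.5; SVM decision values at 0
  cut <- if (object$kind %in% c("mlp3", "linear_reg", "logistic_reg")) 0.5 else 0
  as.integer(score >= cut)
}

#' Flatten volumes to baseline feature vectors
#'
#' Masked voxels of the (optionally 2x2x2 mean-pooled) volume, giving the
#' baseline models the same information source as the network at a
#' tractable dimensionality.
#'
#' @param volumes List of [brain_volume()] objects sharing a mask.
#' @param pool Mean-pool by 2 along each axis before masking.
#' @return Matrix, one row per volume.
#' @export
baseline_features <- function(volumes, pool = TRUE) {
  if (!pool) return(t(masked_matrix(volumes)))
  d <- dim(volumes[[1]]$data)
  pooled_mask <- .pool2_mean(volumes[[1]]$mask * 1) > 0.5
  feats <- vapply(volumes, function(v) .pool2_mean(v$data)[pooled_mask],
                  numeric(sum(pooled_mask)))
  t(feats)
}

.pool2_mean <- function(a) {
  d <- dim(a)
  m <- d %/% 2L
  a <- a[seq_len(2 * m[1]), seq_len(2 * m[2]), seq_len(2 * m[3]), drop = FALSE]
  dim(a) <- c(2L, m[1], 2L, m[2], 2L, m[3])
  out <- apply(a, c(2, 4, 6), mean)
  out
}
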