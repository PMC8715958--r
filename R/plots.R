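#' Plot triage group counts
#'
#' @param cohort A triaged cohort.
#' @return A ggplot.
#' @export
plot_triage <- function(cohort) {
  s <- triage_summary(cohort)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$label, y = .data$n, fill = .data$label)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)", .data$n,
                                                    100 * .data$fraction)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "samples", title = "Triage of the memory tests") +
    ggplot2::theme_minimal()
}

#' Plot longitudinal trajectories with fitted trends
#'
#' Binned group means with OLS trend lines and 95% confidence ribbons.
#'
#' @param visits Visit tibble.
#' @param diagnoses Tibble with `sample_id`/`id` and `diagnosis`.
#' @param test Score column.
#' @return A ggplot.
#' @export
plot_trend <- function(visits, diagnoses,
                       test = c("cdr_memory", "mmse_recall", "adas_recall")) {
  test <- match.arg(test)
  if ("id" %in% names(diagnoses) && !"sample_id" %in% names(diagnoses)) {
    diagnoses <- dplyr::rename(diagnoses, sample_id = "id")
  }
  df <- dplyr::inner_join(visits, diagnoses[c("sample_id", "diagnosis")],
                          by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$months, y = .data[[test]],
                                   colour = .data$diagnosis)) +
    ggplot2::stat_summary(fun = mean, geom = "point", size = 1.5) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95,
                         linewidth = 0.6, alpha = 0.2) +
    ggplot2::labs(x = "months after baseline", y = test,
                  title = "Longitudinal decline by diagnosis") +
    ggplot2::theme_minimal()
}

#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  y <- object$samples$label
  s <- object$samples$score
  ord <- order(s, decreasing = TRUE)
  tpr <- cumsum(y[ord] == 1) / sum(y == 1)
  fpr <- cumsum(y[ord] == 0) / sum(y == 0)
  df <- tibble::tibble(fpr = c(0, fpr), tpr = c(0, tpr))
  ggplot2::ggplot(df, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("Pooled ROC (AUC = %.3f)", object$pooled_auc)) +
    ggplot2::theme_minimal()
}

#' @method autoplot stat_map
#' @export
autoplot.stat_map <- function(object, slice = NULL, method = NULL, ...) {
  d <- dim(object$t)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
  df$t <- as.vector(object$t[, , slice])
  if (!is.null(method) && method %in% names(object$sig)) {
    df$t[!as.vector(object$sig[[method]][, , slice])] <- NA
  }
  df$t[!as.vector(object$mask[, , slice])] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$t)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("t-map, axial slice %d (df = %d)", slice, object$df)) +
    ggplot2::theme_minimal()
}

#' @method autoplot petriage_embedding
#' @export
autoplot.petriage_embedding <- function(object, groups = NULL, ...) {
  df <- object
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2))
  p <- if (is.null(groups)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group), alpha = 0.7)
  }
  p + ggplot2::labs(title = sprintf("%s embedding of network features",
                                    toupper(attr(object, "method")))) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
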