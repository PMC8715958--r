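#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a cross-validation result
#'
#' One row per fold with the confusion counts and percentage metrics.
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  x$fold_metrics
}

#' @rdname tidy.cv_result
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(classifier = x$classifier, k = x$k),
    x$pooled_metrics,
    tibble::tibble(auc = 100 * x$pooled_auc,
                   n = nrow(x$samples))
  )
}

#' Tidy a repeated-subsampling ANOVA result
#'
#' One row per effect with the mean p-value over repeats.
#'
#' @param x An `anova_result`.
#' @param ... Unused.
#' @method tidy anova_result
#' @export
tidy.anova_result <- function(x, ...) {
  tibble::tibble(
    effect = names(x$mean_p),
    mean_p = unname(x$mean_p),
    prop_significant = vapply(
      c("p_certainty", "p_impairment", "p_interaction"),
      function(cl) mean(x$p_values[[cl]] < 0.05, na.rm = TRUE), numeric(1)
    )
  )
}

#' @rdname tidy.anova_result
#' @method glance anova_result
#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(repeats = x$repeats, subsample_size = x$subsample_size,
                 response = x$response)
}

#' Tidy a thresholded statistical map
#'
#' One row per significance method with surviving voxel counts.
#'
#' @param x A `stat_map`.
#' @param ... Unused.
#' @method tidy stat_map
#' @export
tidy.stat_map <- function(x, ...) {
  if (length(x$sig) == 0) {
    return(tibble::tibble(method = character(), n_voxels = integer(),
                          fraction_of_mask = numeric()))
  }
  tibble::tibble(
    method = names(x$sig),
    n_voxels = vapply(x$sig, sum, integer(1)),
    fraction_of_mask = vapply(x$sig, sum, integer(1)) / x$V
  )
}

#' @rdname tidy.stat_map
#' @method glance stat_map
#' @export
glance.stat_map <- function(x, ...) {
  tibble::tibble(V = x$V, df = x$df, t_max = max(x$t[x$mask]),
                 t_min = min(x$t[x$mask]))
}
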