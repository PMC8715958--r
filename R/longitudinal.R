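#' Assign visits to 6-month bins
#'
#' Bins are the multiples of `interval` in `[interval, horizon]` (16 bins
#' for the default 6/96). Each visit goes to the nearest bin; an exact
#' midpoint goes to the lower bin; visits beyond `horizon + interval/2`
#' (or nearer to 0 than to the first bin) are dropped.
#'
#' @param visits Tibble with a `months` column (>= 0).
#' @param interval,horizon Binning grid in months.
#' @return The visits with a `bin` column, restricted to binned rows.
#' @examples
#' bin_visits(tibble::tibble(months = c(14, 15, 16)))$bin
#' @export
bin_visits <- function(visits, interval = 6, horizon = 96) {
  if (interval <= 0) stop_petriage("`interval` must be > 0.", "petriage_parameter_error")
  if (any(visits$months < 0)) {
    stop_petriage("negative months are invalid.", "petriage_validation_error")
  }
  k_low <- floor(visits$months / interval)
  frac <- visits$months - k_low * interval
  k <- ifelse(frac > interval / 2, k_low + 1, k_low)
  bin <- k * interval
  visits$bin <- bin
  dplyr::filter(visits, .data$bin >= interval, .data$bin <= horizon)
}

#' Per-bin group comparison of a longitudinal score
#'
#' Welch two-sample t-test between diagnosed-impaired and diagnosed-healthy
#' samples within each time bin, with Bonferroni family-wise correction
#' over the bins actually evaluated for this score. Bins where either group
#' has fewer than two visits are skipped and listed.
#'
#' @param binned_visits Output of [bin_visits()].
#' @param diagnoses Tibble with `id` (or `sample_id`) and `diagnosis`
#'   (`"impaired"`/`"healthy"`).
#' @param test Score column to compare.
#' @param alpha Base significance level before correction.
#' @return Tibble: per bin, group sizes, `t`, `df`, `p`, `p_fwe` and the
#'   significance tier (`"***"` p < 0.001, `"**"` < 0.01, `"*"` < 0.05,
#'   corrected); skipped bins carry `NA` statistics.
#' @export
timepoint_tests <- function(binned_visits, diagnoses,
                            test = c("cdr_memory", "mmse_recall", "adas_recall"),
                            alpha = 0.05) {
  test <- match.arg(test)
  if (!"bin" %in% names(binned_visits)) {
    stop_petriage("visits are not binned; call bin_visits() first.",
                  "petriage_validation_error")
  }
  if ("id" %in% names(diagnoses) && !"sample_id" %in% names(diagnoses)) {
    diagnoses <- dplyr::rename(diagnoses, sample_id = "id")
  }
  df <- dplyr::inner_join(binned_visits, diagnoses[c("sample_id", "diagnosis")],
                          by = "sample_id")
  df <- dplyr::filter(df, .data$diagnosis %in% c("impaired", "healthy"))

  res <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::group_modify(function(d, key) {
      xi <- d[[test]][d$diagnosis == "impaired"]
      xh <- d[[test]][d$diagnosis == "healthy"]
      evaluable <- length(xi) >= 2 && length(xh) >= 2 &&
        (stats::var(xi) + stats::var(xh)) > 0
      if (!evaluable) {
        return(tibble::tibble(n_impaired = length(xi), n_healthy = length(xh),
                              t = NA_real_, df = NA_real_, p = NA_real_,
                              skipped = TRUE))
      }
      tt <- stats::t.test(xi, xh)
      tibble::tibble(n_impaired = length(xi), n_healthy = length(xh),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value, skipped = FALSE)
    }) |>
    dplyr::ungroup()

  m <- sum(!res$skipped)
  if (m == 0) {
    stop_petriage("no bin had both diagnosis groups evaluable.",
                  "petriage_empty_result_error")
  }
  res$p_fwe <- pmin(res$p * m, 1)
  res$significance <- dplyr::case_when(
    res$skipped ~ NA_character_,
    res$p_fwe < 0.001 ~ "***",
    res$p_fwe < 0.01 ~ "**",
    res$p_fwe < alpha ~ "*",
    TRUE ~ ""
  )
  attr(res, "n_tests") <- m
  attr(res, "score") <- test
  res
}

#' Ordinary least-squares trend of a longitudinal score
#'
#' Fits score ~ months and reports the slope with its 95% confidence
#' interval (`slope +/- t(0.975, n-2) * SE`).
#'
#' @param visits Visit tibble for one group of samples.
#' @param test Score column.
#' @return One-row tibble: `slope`, `intercept`, `ci_lo`, `ci_hi`, `se`,
#'   `n`, `df`.
#' @export
fit_trend <- function(visits, test = c("cdr_memory", "mmse_recall", "adas_recall")) {
  test <- match.arg(test)
  y <- visits[[test]]
  m <- visits$months
  ok <- is.finite(y) & is.finite(m)
  y <- y[ok]; m <- m[ok]
  if (length(y) < 3L || length(unique(m)) < 2L) {
    stop_petriage("trend fitting needs >= 3 visits spanning >= 2 distinct months.",
                  "petriage_insufficient_data_error")
  }
  fit <- stats::lm(y ~ m)
  slope <- unname(stats::coef(fit)[2])
  dfres <- fit$df.residual
  # direct normal-equations standard error (stays quiet on perfect fits)
  xtxinv <- chol2inv(qr.R(fit$qr))
  se <- sqrt(sum(stats::residuals(fit)^2) / dfres * xtxinv[2, 2])
  tcrit <- stats::qt(0.975, dfres)
  tibble::tibble(
    slope = slope, intercept = unname(stats::coef(fit)[1]),
    ci_lo = slope - tcrit * se, ci_hi = slope + tcrit * se,
    se = se, n = length(y), df = dfres, score = test
  )
}

#' Within-subject longitudinal stability
#'
#' Sample SD of each subject's repeated scores (subjects with >= 2 visits),
#' per test, compared between energetic and non-energetic subjects by a
#' Welch t-test.
#'
#' @param visits Visit tibble.
#' @param cohort Cohort tibble providing `id` and `energetic`.
#' @param tests Score columns to summarise.
#' @return List with `per_subject` (tibble of SDs) and `comparison`
#'   (per-test Welch t between energy groups).
#' @export
stability_sd <- function(visits, cohort,
                         tests = c("mmse_recall", "adas_recall", "cdr_memory")) {
  per_subject <- visits |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::filter(dplyr::n() >= 2) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(tests), stats::sd),
                     n_visits = dplyr::n(), .groups = "drop")
  if (nrow(per_subject) == 0) {
    stop_petriage("no subject has >= 2 visits.", "petriage_empty_result_error")
  }
  per_subject <- dplyr::inner_join(
    per_subject, dplyr::select(cohort, sample_id = "id", "energetic"),
    by = "sample_id"
  )
  comparison <- purrr::map_dfr(tests, function(tst) {
    se <- per_subject[[tst]][per_subject$energetic]
    sn <- per_subject[[tst]][!per_subject$energetic]
    base <- tibble::tibble(score = tst,
                           mean_sd_energetic = mean(se),
                           mean_sd_nonenergetic = mean(sn))
    if (length(se) < 2 || length(sn) < 2) {  # group too small to compare
      return(dplyr::mutate(base, t = NA_real_, df = NA_real_, p = NA_real_))
    }
    tt <- stats::t.test(sn, se)
    dplyr::mutate(base, t = unname(tt$statistic), df = unname(tt$parameter),
                  p = tt$p.value)
  })
  list(per_subject = per_subject, comparison = comparison)
}
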