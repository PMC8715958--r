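#' Triage thresholds for the three memory tests
#'
#' The concordance rule: a case is *certain impaired* iff MMSE-Recall <= 1,
#' ADAS-Cog-Recall < `adas_low` and CDR-Memory >= 1; *certain healthy* iff
#' MMSE-Recall > 1, ADAS-Cog-Recall > `adas_high` and CDR-Memory = 0; every
#' other combination conflicts and is *uncertain*. The ADAS cut points
#' default to the published constants 12 and 23 (mean -/+ SD of the
#' baseline ADAS-Cog-Recall distribution); [compute_adas_thresholds()]
#' recomputes them from data.
#'
#' @param mmse_max_impaired,adas_low,adas_high,cdr_min_impaired,cdr_healthy
#'   Score cut points; inequalities are applied exactly as stated above
#'   (strict `<`/`>` on ADAS).
#' @return An object of class `triage_thresholds`.
#' @export
triage_thresholds <- function(mmse_max_impaired = 1, adas_low = 12,
                              adas_high = 23, cdr_min_impaired = 1,
                              cdr_healthy = 0) {
  if (adas_low >= adas_high) {
    stop_petriage("`adas_low` must be < `adas_high`.", "petriage_parameter_error")
  }
  structure(
    list(mmse_max_impaired = mmse_max_impaired, adas_low = adas_low,
         adas_high = adas_high, cdr_min_impaired = cdr_min_impaired,
         cdr_healthy = cdr_healthy),
    class = "triage_thresholds"
  )
}

#' Derive the ADAS-Cog-Recall cut points from a score distribution
#'
#' Returns (mean - SD, mean + SD) with the sample SD (n - 1 denominator),
#' optionally rounded to the nearest integer. Applied to the full baseline
#' ADAS-Cog-Recall distribution this recovers the published 12/23 rule.
#'
#' @param adas_scores Numeric vector of at least two scores.
#' @param rounding `"none"` or `"nearest-integer"`.
#' @return Named numeric vector `c(adas_low, adas_high)`.
#' @examples
#' compute_adas_thresholds(c(12, 17.5, 23))
#' @export
compute_adas_thresholds <- function(adas_scores, rounding = c("none", "nearest-integer")) {
  rounding <- match.arg(rounding)
  adas_scores <- adas_scores[!is.na(adas_scores)]
  if (length(adas_scores) < 2L) {
    stop_petriage("at least two ADAS scores are required.", "petriage_insufficient_data_error")
  }
  m <- mean(adas_scores)
  s <- stats::sd(adas_scores)
  out <- c(adas_low = m - s, adas_high = m + s)
  if (rounding == "nearest-integer") out <- round(out)
  out
}

.check_scores <- function(mmse, adas, cdr) {
  bad <- is.na(mmse) | is.na(adas) | is.na(cdr) |
    mmse < 0 | mmse > 3 | adas < 0 | adas > 30 |
    !(cdr %in% c(0, 0.5, 1, 2, 3))
  bad
}

#' Assign a triage label from the three memory scores
#'
#' Vectorised; exactly one label per triple. Boundary values (e.g.
#' ADAS-Cog-Recall exactly 12 or 23, CDR-Memory 0.5) conflict with the
#' strict certainty conjunctions and fall to `uncertain`.
#'
#' @param mmse_recall Integer 0--3 (words recalled out of 3).
#' @param adas_recall Integer 0--30 (words recalled out of 30; higher is
#'   better under this scoring).
#' @param cdr_memory One of 0, 0.5, 1, 2, 3.
#' @param thresholds A [triage_thresholds()].
#' @return Character vector with values `certain_impaired`,
#'   `certain_healthy` or `uncertain`.
#' @examples
#' assign_group(0, 8, 1)   # all three tests agree: impaired
#' assign_group(3, 25, 0)  # all three tests agree: healthy
#' assign_group(3, 8, 1)   # conflicting: uncertain
#' @export
assign_group <- function(mmse_recall, adas_recall, cdr_memory,
                         thresholds = triage_thresholds()) {
  bad <- .check_scores(mmse_recall, adas_recall, cdr_memory)
  if (any(bad)) {
    stop_petriage(
      sprintf("out-of-range score(s) at position(s): %s",
              paste(utils::head(which(bad), 10), collapse = ", ")),
      "petriage_validation_error"
    )
  }
  th <- thresholds
  impaired <- mmse_recall <= th$mmse_max_impaired &
    adas_recall < th$adas_low & cdr_memory >= th$cdr_min_impaired
  healthy <- mmse_recall > th$mmse_max_impaired &
    adas_recall > th$adas_high & cdr_memory == th$cdr_healthy
  ifelse(impaired, "certain_impaired", ifelse(healthy, "certain_healthy", "uncertain"))
}

#' Triage a whole cohort
#'
#' Sets `triage_label` for every sample and attaches a group-count summary
#' (also retrievable with [triage_summary()]).
#'
#' @param cohort Tibble with columns `mmse_recall`, `adas_recall`,
#'   `cdr_memory` (and ideally `id`).
#' @param thresholds A [triage_thresholds()].
#' @return The cohort with `triage_label` filled in.
#' @export
triage_cohort <- function(cohort, thresholds = triage_thresholds()) {
  need <- c("mmse_recall", "adas_recall", "cdr_memory")
  if (!all(need %in% names(cohort))) {
    stop_petriage("cohort must have mmse_recall, adas_recall and cdr_memory columns.",
                  "petriage_validation_error")
  }
  missing <- !stats::complete.cases(cohort[need])
  if (any(missing)) {
    ids <- if ("id" %in% names(cohort)) cohort$id[missing] else which(missing)
    stop_petriage(
      sprintf("missing memory score(s) for sample(s): %s",
              paste(utils::head(ids, 10), collapse = ", ")),
      "petriage_validation_error"
    )
  }
  cohort$triage_label <- if (nrow(cohort) > 0) {
    assign_group(cohort$mmse_recall, cohort$adas_recall, cohort$cdr_memory, thresholds)
  } else {
    character(0)
  }
  attr(cohort, "triage_summary") <- triage_summary(cohort)
  cohort
}

#' @rdname triage_cohort
#' @export
triage_summary <- function(cohort) {
  labs <- c("certain_impaired", "certain_healthy", "uncertain")
  counts <- unname(vapply(labs, function(l) sum(cohort$triage_label == l), integer(1)))
  tibble::tibble(
    label = labs,
    n = counts,
    fraction = if (nrow(cohort) > 0) counts / nrow(cohort) else rep(NA_real_, 3)
  )
}
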