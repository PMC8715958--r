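#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the downstream analysis assumes:
#' group proportions 312/333/1741 out of 2,386 (certain-impaired /
#' certain-healthy / uncertain), per-group score and demographic moments,
#' monthly CDR-Memory slope ranges of 0.0046--0.0076 (impaired) and
#' 0.0011--0.0020 (healthy), and per-group "full of energy" proportions
#' 80.27% / 76.44% / 69.55%.
#'
#' @param n_samples Number of baseline samples to generate.
#' @param group_proportions Fractions (certain_impaired, certain_healthy,
#'   uncertain) summing to 1.
#' @param score_params Per-group mean/SD for the three memory scores; see the
#'   default for the expected structure.
#' @param demo_params Per-group demographic parameters (age, education,
#'   female and ApoE4 proportions).
#' @param slope_ranges Per-true-state interval (per month) from which each
#'   sample's CDR-Memory slope is drawn uniformly.
#' @param decline_rates Monthly drift of MMSE-Recall and ADAS-Cog-Recall per
#'   true state (both tests decline, i.e. fewer words recalled).
#' @param visit_noise Per-test SD of the visit-level observation noise.
#' @param nonenergetic_noise_factor Multiplier applied to `visit_noise` for
#'   non-energetic subjects (emulates their less stable test performance).
#' @param gds_energy_props Per-group probability of answering "yes" to the
#'   GDS energy item.
#' @param gds_memory_props Probability of a depression-keyed GDS memory
#'   response per true state.
#' @param gds_other_prop Bernoulli rate of the remaining GDS items.
#' @param mild_severity Metabolic effect severity of uncertain-impaired
#'   samples relative to certain-impaired (in (0, 1)).
#' @param volume_params Phantom volume parameters: `grid_edge`, `voxel_mm`,
#'   `baseline` intensity, AD effect fraction `delta_ad`, depression effect
#'   fraction `delta_dep`, `noise_sd`, `pons` intensity.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 2000L,
                             group_proportions = c(certain_impaired = 312,
                                                   certain_healthy = 333,
                                                   uncertain = 1741) / 2386,
                             score_params = default_score_params(),
                             demo_params = default_demo_params(),
                             slope_ranges = list(impaired = c(0.0046, 0.0076),
                                                 healthy = c(0.0011, 0.0020)),
                             decline_rates = list(
                               mmse = c(impaired = -0.017, healthy = -0.006),
                               adas = c(impaired = -0.045, healthy = -0.012)
                             ),
                             visit_noise = c(mmse = 0.3, adas = 1.5, cdr = 0.15),
                             nonenergetic_noise_factor = 1.5,
                             gds_energy_props = c(certain_impaired = 0.8027,
                                                  certain_healthy = 0.7644,
                                                  uncertain = 0.6955),
                             gds_memory_props = c(impaired = 0.5, healthy = 0.1),
                             gds_other_prop = 0.1,
                             mild_severity = 0.5,
                             volume_params = list(grid_edge = 32L, voxel_mm = 2,
                                                  baseline = 1.2, delta_ad = 0.15,
                                                  delta_dep = 0.08, noise_sd = 0.05,
                                                  pons = 1.0),
                             seed = 1L) {
  cfg <- structure(
    list(
      n_samples = as.integer(n_samples),
      group_proportions = group_proportions,
      score_params = score_params,
      demo_params = demo_params,
      slope_ranges = slope_ranges,
      decline_rates = decline_rates,
      visit_noise = visit_noise,
      nonenergetic_noise_factor = nonenergetic_noise_factor,
      gds_energy_props = gds_energy_props,
      gds_memory_props = gds_memory_props,
      gds_other_prop = gds_other_prop,
      mild_severity = mild_severity,
      volume_params = volume_params,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
  validate_generator_config(cfg)
}

#' @rdname generator_config
#' @export
default_score_params <- function() {
  tibble::tribble(
    ~group,             ~score,        ~mean, ~sd,
    "certain_impaired", "mmse_recall",  0.19, 0.39,
    "certain_impaired", "adas_recall",  8.49, 2.45,
    "certain_impaired", "cdr_memory",   1.36, 0.51,
    "certain_healthy",  "mmse_recall",  2.87, 0.33,
    "certain_healthy",  "adas_recall", 25.02, 1.84,
    "certain_healthy",  "cdr_memory",   0.00, 0.00,
    "uncertain",        "mmse_recall",  2.02, 1.09,
    "uncertain",        "adas_recall", 17.54, 3.92,
    "uncertain",        "cdr_memory",   0.49, 0.35
  )
}

#' @rdname generator_config
#' @export
default_demo_params <- function() {
  tibble::tribble(
    ~group,             ~age_mean, ~age_sd, ~female_prop, ~edu_mean, ~edu_sd, ~apoe4_prop,
    "certain_impaired",     75.68,    7.26,       0.4135,      6.50,    3.40,      0.6827,
    "certain_healthy",      74.58,    5.87,       0.5225,      6.75,    3.39,      0.2169,
    "uncertain",            75.65,    7.46,       0.3837,      6.57,    3.42,      0.4597
  )
}

#' @rdname generator_config
#' @export
validate_generator_config <- function(cfg) {
  gp <- cfg$group_proportions
  if (length(gp) != 3L || abs(sum(gp) - 1) > 1e-9 || any(gp < 0)) {
    stop_petriage("`group_proportions` must be three non-negative fractions summing to 1.",
                  "petriage_config_error")
  }
  if (any(cfg$score_params$sd < 0)) {
    stop_petriage("score SDs must be >= 0.", "petriage_config_error")
  }
  vp <- cfg$volume_params
  for (d in c("delta_ad", "delta_dep")) {
    if (vp[[d]] < 0 || vp[[d]] >= 1) {
      stop_petriage(sprintf("`%s` must lie in [0, 1).", d), "petriage_config_error")
    }
  }
  if (vp$noise_sd < 0) stop_petriage("`noise_sd` must be >= 0.", "petriage_config_error")
  if (cfg$mild_severity < 0 || cfg$mild_severity >= 1) {
    stop_petriage("`mild_severity` must lie in [0, 1).", "petriage_config_error")
  }
  for (s in names(cfg$slope_ranges)) {
    r <- cfg$slope_ranges[[s]]
    if (length(r) != 2L || r[1] > r[2]) {
      stop_petriage("slope ranges must be ordered intervals.", "petriage_config_error")
    }
  }
  invisible(cfg)
}

.gds_items <- function() {
  c("satisfy", "drop", "empty", "bored", "spirit", "afraid", "happy", "help",
    "home", "memory", "alive", "worth", "energy", "hope", "better")
}

#' GDS item column names
#'
#' The 15 geriatric depression scale items, as `gds_<item>` column names.
#' Each column stores the depression-keyed response (1 = depressive answer),
#' so `gds_total` is simply their row sum. The energy item is the negation
#' of `energetic` ("Do you feel full of energy?").
#'
#' @return Character vector of 15 column names.
#' @export
gds_item_columns <- function() paste0("gds_", .gds_items())

# Draw one group's worth of score triples, resampling each sample until the
# triage rule reproduces the intended label (max 1000 draws per sample).
.draw_scores_for_group <- function(n, group, params, thresholds) {
  pr <- function(score) params[params$score == score, ]
  mm <- pr("mmse_recall"); ad <- pr("adas_recall"); cd <- pr("cdr_memory")
  cdr_support <- c(0, 0.5, 1, 2, 3)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("mmse", "adas", "cdr")))
  todo <- seq_len(n)
  for (attempt in seq_len(1000L)) {
    m <- length(todo)
    if (m == 0L) break
    mmse <- clip(round(stats::rnorm(m, mm$mean, mm$sd)), 0, 3)
    adas <- clip(round(stats::rnorm(m, ad$mean, ad$sd)), 0, 30)
    cdr <- snap_to(stats::rnorm(m, cd$mean, cd$sd), cdr_support)
    lab <- assign_group(mmse, adas, cdr, thresholds)
    ok <- lab == group
    out[todo[ok], ] <- cbind(mmse[ok], adas[ok], cdr[ok])
    todo <- todo[!ok]
  }
  if (length(todo) > 0L) {
    stop_petriage(
      sprintf("could not draw scores consistent with intended label '%s' within 1000 attempts; score parameters conflict with the triage thresholds.", group),
      "petriage_config_error"
    )
  }
  out
}

#' Generate a synthetic baseline cohort
#'
#' Draws one row per sample: an intended triage group (by the configured
#' proportions), memory scores from that group's truncated-and-rounded
#' normal distributions resampled until the fixed 12/23 triage rule
#' reproduces the intended label, demographics, a latent true impairment
#' state, the energy state, and the 15 GDS items. Uncertain samples get
#' their true state from a latent severity draw `u ~ Uniform(0, 1)`
#' (impaired iff `u > 0.5`); certain samples' true state matches their label.
#'
#' @param config A [generator_config()].
#' @param thresholds Triage thresholds used for the consistency resampling
#'   (the printed 12/23 rule by default).
#' @return A tibble of class `petriage_cohort`, one row per sample.
#' @examples
#' cohort <- generate_cohort(generator_config(n_samples = 50, seed = 7))
#' dplyr::count(cohort, group)
#' @export
generate_cohort <- function(config = generator_config(),
                            thresholds = triage_thresholds()) {
  validate_generator_config(config)
  with_seed(config$seed, {
    n <- config$n_samples
    groups <- c("certain_impaired", "certain_healthy", "uncertain")
    # deterministic counts closest to the configured proportions
    counts <- floor(config$group_proportions * n)
    rem <- n - sum(counts)
    if (rem > 0) {
      frac <- config$group_proportions * n - counts
      counts[order(frac, decreasing = TRUE)[seq_len(rem)]] <-
        counts[order(frac, decreasing = TRUE)[seq_len(rem)]] + 1
    }
    group <- sample(rep(groups, counts))

    score_mat <- matrix(NA_real_, n, 3)
    for (g in groups) {
      sel <- group == g
      if (!any(sel)) next
      score_mat[sel, ] <- .draw_scores_for_group(
        sum(sel), g, config$score_params[config$score_params$group == g, ], thresholds
      )
    }

    dp <- config$demo_params[match(group, config$demo_params$group), ]
    severity_u <- stats::runif(n)
    true_state <- ifelse(
      group == "certain_impaired", "impaired",
      ifelse(group == "certain_healthy", "healthy",
             ifelse(severity_u > 0.5, "impaired", "healthy"))
    )
    energetic <- stats::rbinom(n, 1, unname(config$gds_energy_props[group])) == 1

    gds <- matrix(0L, n, 15, dimnames = list(NULL, gds_item_columns()))
    for (item in .gds_items()) {
      col <- paste0("gds_", item)
      p <- switch(item,
        energy = as.numeric(!energetic), # keyed response is "not energetic"
        memory = unname(config$gds_memory_props[true_state]),
        config$gds_other_prop
      )
      gds[, col] <- stats::rbinom(n, 1, p)
    }

    cohort <- tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      group = group,
      age = round(stats::rnorm(n, dp$age_mean, dp$age_sd), 1),
      sex = ifelse(stats::rbinom(n, 1, dp$female_prop) == 1, "F", "M"),
      education = clip(round(stats::rnorm(n, dp$edu_mean, dp$edu_sd)), 0, 20),
      apoe4 = ifelse(stats::rbinom(n, 1, dp$apoe4_prop) == 1, "carrier", "non-carrier"),
      mmse_recall = score_mat[, 1],
      adas_recall = score_mat[, 2],
      cdr_memory = score_mat[, 3],
      true_state = true_state,
      severity_u = severity_u,
      energetic = energetic
    )
    cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(gds))
    cohort$gds_total <- as.integer(rowSums(gds))
    cohort$triage_label <- "unassigned"
    cohort$diagnosis <- "none"
    cohort$diagnosis_prob <- NA_real_
    class(cohort) <- c("petriage_cohort", class(cohort))
    cohort
  })
}

#' Generate longitudinal visit records
#'
#' Each sample receives visits at every multiple of `interval` months in
#' `[interval, horizon]`. The CDR-Memory trajectory has a per-sample slope
#' drawn uniformly from the true state's configured range; MMSE-Recall and
#' ADAS-Cog-Recall decline at the state's configured monthly rate. Visit
#' noise is Gaussian per test, inflated by `nonenergetic_noise_factor` for
#' non-energetic subjects, and scores are clipped to their ranges.
#'
#' @param cohort Cohort tibble with `true_state` and `energetic` per sample.
#' @param interval,horizon Visit schedule in months.
#' @param config The same [generator_config()] used for the cohort.
#' @param noise_scale Multiplier on visit noise (0 gives noise-free lines).
#' @return A tibble of visit records: `sample_id`, `months`, the three
#'   scores, plus the latent `slope_cdr` drawn for each sample.
#' @export
generate_longitudinal <- function(cohort, interval = 6, horizon = 96,
                                  config = generator_config(),
                                  noise_scale = 1) {
  if (interval <= 0 || horizon < interval) {
    stop_petriage("`interval` must be > 0 and `horizon` >= `interval`.",
                  "petriage_parameter_error")
  }
  if (!all(c("true_state", "energetic") %in% names(cohort))) {
    stop_petriage("cohort must carry `true_state` and `energetic`.",
                  "petriage_validation_error")
  }
  with_seed(config$seed + 1L, {
    months <- seq(interval, horizon, by = interval)
    n <- nrow(cohort)
    sr <- config$slope_ranges
    slope <- ifelse(
      cohort$true_state == "impaired",
      stats::runif(n, sr$impaired[1], sr$impaired[2]),
      stats::runif(n, sr$healthy[1], sr$healthy[2])
    )
    rate_m <- unname(config$decline_rates$mmse[cohort$true_state])
    rate_a <- unname(config$decline_rates$adas[cohort$true_state])
    noise_fac <- ifelse(cohort$energetic, 1, config$nonenergetic_noise_factor) * noise_scale

    visits <- tidyr::expand_grid(i = seq_len(n), months = months)
    i <- visits$i
    m <- visits$months
    nf <- noise_fac[i]
    visits <- tibble::tibble(
      sample_id = cohort$id[i],
      months = m,
      mmse_recall = clip(cohort$mmse_recall[i] + rate_m[i] * m +
                           stats::rnorm(length(i), 0, config$visit_noise[["mmse"]] * nf), 0, 3),
      adas_recall = clip(cohort$adas_recall[i] + rate_a[i] * m +
                           stats::rnorm(length(i), 0, config$visit_noise[["adas"]] * nf), 0, 30),
      cdr_memory = clip(cohort$cdr_memory[i] + slope[i] * m +
                          stats::rnorm(length(i), 0, config$visit_noise[["cdr"]] * nf), 0, 3),
      slope_cdr = slope[i]
    )
    visits
  })
}
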