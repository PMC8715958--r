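# Build the design matrix [intercept, group, covariates] and check rank.
.build_design <- function(group, covariates = NULL, n) {
  g <- .coerce_labels(group)
  if (length(g) != n) stop_petriage("group length mismatch.", "petriage_design_error")
  X <- cbind(intercept = 1, group = g)
  if (!is.null(covariates)) {
    cv <- as.data.frame(covariates)
    for (nm in names(cv)) {
      col <- cv[[nm]]
      if (is.character(col) || is.factor(col)) {
        col <- as.integer(factor(col)) - 1L  # binary coding (0/1 for 2 levels)
      }
      X <- cbind(X, stats::setNames(data.frame(col), nm))
    }
    X <- as.matrix(X)
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_petriage(sprintf("design is rank deficient; collinear column(s): %s.",
                          paste(dropped, collapse = ", ")),
                  "petriage_design_error")
  }
  X
}

#' Voxelwise general linear model t-map
#'
#' Per in-mask voxel, least-squares regression of intensity on
#' [intercept, group, covariates]; the map holds the t statistic of the
#' group coefficient with `df = n - p` degrees of freedom. With no
#' covariates this reduces exactly to the pooled-variance two-sample
#' t-test.
#'
#' @param volumes List of aligned [brain_volume()]s sharing a mask.
#' @param group Binary factor (1/`"impaired"` = positive); the t sign is
#'   positive where the positive group has *higher* intensity.
#' @param covariates Optional data frame (e.g. age, sex, education, ApoE4);
#'   two-level character/factor columns are coded 0/1.
#' @param mask Analysis mask (defaults to the volumes' own mask).
#' @return Object of class `stat_map`: `t` (3-D array, 0 outside the
#'   mask), `df`, `mask`, `V`, and an initially empty `sig` list.
#' @export
glm_tmap <- function(volumes, group, covariates = NULL, mask = NULL) {
  mask <- mask %||% volumes[[1]]$mask
  Y <- t(masked_matrix(volumes, mask))  # n x V
  n <- nrow(Y)
  X <- .build_design(group, covariates, n)
  p <- ncol(X)
  if (n <= p) stop_petriage("more design columns than samples.", "petriage_design_error")
  XtXinv <- solve(crossprod(X))
  beta <- XtXinv %*% crossprod(X, Y)           # p x V
  resid <- Y - X %*% beta
  sigma2 <- colSums(resid^2) / (n - p)
  se <- sqrt(sigma2 * XtXinv[2, 2])
  tval <- ifelse(se > 0, beta[2, ] / se, 0)
  tarr <- array(0, dim(mask))
  tarr[which(mask)] <- tval
  structure(
    list(t = tarr, df = n - p, mask = mask, V = sum(mask), sig = list(),
         voxel_mm = volumes[[1]]$voxel_mm),
    class = "stat_map"
  )
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %d in-mask voxels, df = %d, |t| max = %.2f, masks: %s\n",
              x$V, x$df, max(abs(x$t[x$mask])),
              if (length(x$sig)) paste(names(x$sig), collapse = ", ") else "none"))
  invisible(x)
}

# Two-sided p-values of the in-mask t statistics.
.map_pvalues <- function(map) 2 * stats::pt(-abs(map$t[which(map$mask)]), map$df)

#' Threshold a t-map with multiplicity control
#'
#' `"fwe"` applies Bonferroni (two-sided per-voxel threshold
#' `alpha / V` over the in-mask voxel count); `"fdr"` applies the
#' Benjamini-Hochberg step-up rule (reject while `p(k) <= k * alpha / m`)
#' over the in-mask two-sided p-values.
#'
#' @param map A [glm_tmap()] result.
#' @param method `"fwe"` or `"fdr"`.
#' @param alpha Significance level in (0, 1).
#' @return The map with `sig[[method]]` set (a logical array) and the
#'   per-voxel threshold recorded in `sig_info`.
#' @export
threshold_map <- function(map, method = c("fwe", "fdr"), alpha = 0.05) {
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) {
    stop_petriage("`alpha` must lie in (0, 1).", "petriage_parameter_error")
  }
  pvals <- .map_pvalues(map)
  keep <- if (method == "fwe") {
    pvals < alpha / map$V
  } else {
    stats::p.adjust(pvals, method = "BH") <= alpha
  }
  sig <- array(FALSE, dim(map$mask))
  sig[which(map$mask)[keep]] <- TRUE
  map$sig[[method]] <- sig
  map$sig_info[[method]] <- list(alpha = alpha,
                                 voxel_threshold = if (method == "fwe") alpha / map$V else NA)
  map
}

.connectivity_offsets <- function(connectivity) {
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nz <- rowSums(abs(offs))
  switch(as.character(connectivity),
         "6" = offs[nz == 1, , drop = FALSE],
         "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
         "26" = offs[nz >= 1, , drop = FALSE],
         stop_petriage("connectivity must be 6, 18 or 26.", "petriage_parameter_error"))
}

#' Filter a significance mask by cluster extent
#'
#' Connected components under the chosen neighbourhood (18-connectivity by
#' default: faces and edges, not corners); only clusters with *more than*
#' `min_extent` voxels survive.
#'
#' @param mask Logical 3-D array.
#' @param min_extent Strict lower bound on surviving cluster size.
#' @param connectivity 6, 18 or 26.
#' @param t Optional t array for peak localisation.
#' @return List with `mask` (filtered) and `clusters` (tibble: id, size,
#'   kept flag, peak voxel coordinates).
#' @export
cluster_filter <- function(mask, min_extent = 5, connectivity = 18, t = NULL) {
  d <- dim(mask)
  offs <- .connectivity_offsets(connectivity)
  labels <- array(0L, d)
  nextid <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (labels[start] != 0L) next
    nextid <- nextid + 1L
    queue <- start
    labels[start] <- nextid
    while (length(queue) > 0) {
      cur <- queue
      queue <- integer(0)
      co <- arrayInd(cur, d)
      for (k in seq_len(nrow(offs))) {
        p1 <- co[, 1] + offs[k, 1]; p2 <- co[, 2] + offs[k, 2]; p3 <- co[, 3] + offs[k, 3]
        ok <- p1 >= 1 & p1 <= d[1] & p2 >= 1 & p2 <= d[2] & p3 >= 1 & p3 <= d[3]
        if (!any(ok)) next
        lin <- (p3[ok] - 1L) * d[1] * d[2] + (p2[ok] - 1L) * d[1] + p1[ok]
        lin <- lin[mask[lin] & labels[lin] == 0L]
        if (length(lin)) {
          labels[lin] <- nextid
          queue <- c(queue, lin)
        }
      }
      queue <- unique(queue)
    }
  }
  if (nextid == 0L) {
    return(list(mask = mask & FALSE,
                clusters = tibble::tibble(id = integer(), size = integer(),
                                          kept = logical(), peak_x = integer(),
                                          peak_y = integer(), peak_z = integer())))
  }
  sizes <- tabulate(labels[idx_all], nbins = nextid)
  kept_ids <- which(sizes > min_extent)
  out_mask <- array(labels %in% kept_ids, d)
  clusters <- purrr::map_dfr(seq_len(nextid), function(i) {
    vox <- which(labels == i)
    peak <- if (!is.null(t)) vox[which.max(abs(t[vox]))] else vox[1]
    pc <- arrayInd(peak, d)
    tibble::tibble(id = i, size = sizes[i], kept = i %in% kept_ids,
                   peak_x = pc[1], peak_y = pc[2], peak_z = pc[3])
  })
  list(mask = out_mask, clusters = clusters)
}

#' Region-of-interest group comparison
#'
#' Per region: subject-level mean SUVr over the region's voxels, then the
#' same general linear model as [glm_tmap()] (group coefficient t-test with
#' covariates), Bonferroni-corrected across the regions tested. Empty
#' regions are excluded from the correction count with a warning.
#'
#' @param volumes List of aligned volumes.
#' @param atlas A [build_atlas()] result.
#' @param group Binary factor as in [glm_tmap()].
#' @param covariates Optional covariate data frame.
#' @param rois Regions to test (defaults to all cerebral regions).
#' @return Tibble: per region, group means, `t`, `df`, `p`, `p_fwe`,
#'   `significant` (at corrected 0.05).
#' @export
roi_compare <- function(volumes, atlas, group, covariates = NULL, rois = NULL) {
  rois <- rois %||% setdiff(names(atlas$names), "pons")
  g <- .coerce_labels(group)
  means <- lapply(rois, function(r) {
    m <- atlas_mask(atlas, r)
    if (!any(m)) {
      warning(sprintf("region '%s' is empty; excluded.", r))
      return(NULL)
    }
    idx <- which(m)
    vapply(volumes, function(v) mean(v$data[idx]), numeric(1))
  })
  names(means) <- rois
  means <- means[!vapply(means, is.null, logical(1))]
  m_tests <- length(means)
  out <- purrr::imap_dfr(means, function(vals, r) {
    X <- .build_design(g, covariates, length(vals))
    p <- ncol(X)
    XtXinv <- solve(crossprod(X))
    beta <- XtXinv %*% crossprod(X, vals)
    resid <- vals - as.numeric(X %*% beta)
    sigma2 <- sum(resid^2) / (length(vals) - p)
    se <- sqrt(sigma2 * XtXinv[2, 2])
    tval <- if (se > 0) beta[2, 1] / se else 0
    pval <- 2 * stats::pt(-abs(tval), length(vals) - p)
    tibble::tibble(
      roi = r,
      mean_positive = mean(vals[g == 1]), mean_negative = mean(vals[g == 0]),
      t = tval, df = length(vals) - p, p = pval
    )
  })
  out$p_fwe <- pmin(out$p * m_tests, 1)
  out$significant <- out$p_fwe < 0.05
  out
}

#' Certainty and impairment factors of a diagnosed cohort
#'
#' Derives the two analysis factors from a triaged and diagnosed cohort:
#' `certainty` (certain vs uncertain triage) and `impairment` (triage label
#' for certain cases, classifier diagnosis for uncertain ones).
#'
#' @param cohort Cohort with `triage_label` and, for uncertain samples,
#'   `diagnosis`.
#' @return The cohort with `certainty` and `impairment` columns added.
#' @export
final_labels <- function(cohort) {
  if (!"triage_label" %in% names(cohort)) {
    stop_petriage("cohort is not triaged.", "petriage_validation_error")
  }
  cohort$certainty <- ifelse(cohort$triage_label == "uncertain", "uncertain", "certain")
  cohort$impairment <- dplyr::case_when(
    cohort$triage_label == "certain_impaired" ~ "impaired",
    cohort$triage_label == "certain_healthy" ~ "healthy",
    TRUE ~ cohort$diagnosis
  )
  cohort
}

#' GDS item-wise association battery
#'
#' For each of the 15 binary GDS items, a 2x2 chi-squared test (without
#' continuity correction) of item response against the chosen factor; the
#' GDS total is tested by a Welch t-test. The family-wise threshold is
#' `0.05 / 16` (15 items + total), i.e. 0.0031 to two significant figures.
#'
#' @param cohort Cohort carrying the `gds_*` items, `gds_total`, and the
#'   factor columns from [final_labels()].
#' @param factor `"impairment"` or `"certainty"`.
#' @return Tibble: per test, `statistic`, `p`, `significant`; the corrected
#'   threshold is in attribute `"threshold"`.
#' @export
gds_itemwise <- function(cohort, factor = c("impairment", "certainty")) {
  factor <- match.arg(factor)
  if (!factor %in% names(cohort)) cohort <- final_labels(cohort)
  f <- cohort[[factor]]
  lev <- sort(unique(f))
  if (length(lev) != 2L) {
    stop_petriage(sprintf("factor '%s' must have exactly two levels.", factor),
                  "petriage_validation_error")
  }
  items <- gds_item_columns()
  n_tests <- length(items) + 1L
  threshold <- 0.05 / n_tests
  rows <- purrr::map(items, function(col) {
    tab <- table(factor(cohort[[col]], levels = 0:1), f)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) {
      warning(sprintf("item '%s' skipped: a zero expected cell.", col))
      return(tibble::tibble(test = col, statistic = NA_real_, p = NA_real_,
                            method = "chi-squared", skipped = TRUE))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    tibble::tibble(test = col, statistic = unname(ct$statistic),
                   p = ct$p.value, method = "chi-squared", skipped = FALSE)
  })
  tt <- stats::t.test(cohort$gds_total[f == lev[1]], cohort$gds_total[f == lev[2]])
  rows[[length(rows) + 1L]] <- tibble::tibble(
    test = "gds_total", statistic = unname(tt$statistic), p = tt$p.value,
    method = "welch-t", skipped = FALSE
  )
  out <- dplyr::bind_rows(rows)
  out$significant <- !is.na(out$p) & out$p < threshold
  attr(out, "threshold") <- threshold
  attr(out, "factor") <- factor
  out
}

#' Balanced repeated-subsampling two-way ANOVA
#'
#' Cell sizes of the certainty-by-impairment design are unequal, so each
#' repeat draws (without replacement) from every cell down to the smallest
#' cell size, runs a balanced two-way ANOVA with interaction on the
#' response, and records the p-values of both main effects and the
#' interaction; means over repeats are reported.
#'
#' @param cohort Cohort with `certainty` and `impairment` (see
#'   [final_labels()]).
#' @param response Response column (GDS total by default).
#' @param repeats Number of random subsamples.
#' @param seed Subsampling seed.
#' @return Object of class `anova_result`: per-repeat p tibble, mean p per
#'   effect, the subsample cell size and repeat count.
#' @export
anova_subsampled <- function(cohort, response = "gds_total", repeats = 100L,
                             seed = 1L) {
  if (!all(c("certainty", "impairment") %in% names(cohort))) {
    cohort <- final_labels(cohort)
  }
  cells <- split(seq_len(nrow(cohort)),
                 interaction(cohort$certainty, cohort$impairment, drop = FALSE))
  if (length(cells) != 4L || any(lengths(cells) == 0L)) {
    stop_petriage("all four certainty-by-impairment cells must be non-empty.",
                  "petriage_grouping_error")
  }
  m <- min(lengths(cells))
  y_all <- cohort[[response]]
  ps <- with_seed(seed, {
    purrr::map_dfr(seq_len(repeats), function(r) {
      idx <- unlist(lapply(cells, function(cell) {
        if (length(cell) == m) cell else sample(cell, m)
      }), use.names = FALSE)
      d <- data.frame(y = y_all[idx],
                      certainty = cohort$certainty[idx],
                      impairment = cohort$impairment[idx])
      if (stats::var(d$y) == 0) {
        return(tibble::tibble(repeat_i = r, p_certainty = NA_real_,
                              p_impairment = NA_real_, p_interaction = NA_real_))
      }
      av <- stats::anova(stats::lm(y ~ certainty * impairment, data = d))
      tibble::tibble(repeat_i = r,
                     p_certainty = av["certainty", "Pr(>F)"],
                     p_impairment = av["impairment", "Pr(>F)"],
                     p_interaction = av["certainty:impairment", "Pr(>F)"])
    })
  })
  structure(
    list(p_values = ps,
         mean_p = c(certainty = mean(ps$p_certainty),
                    impairment = mean(ps$p_impairment),
                    interaction = mean(ps$p_interaction)),
         subsample_size = m, repeats = repeats, response = response),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> %d repeats at cell size %d; mean p: certainty %.4g, impairment %.4g, interaction %.4g\n",
              x$repeats, x$subsample_size,
              x$mean_p["certainty"], x$mean_p["impairment"], x$mean_p["interaction"]))
  invisible(x)
}
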