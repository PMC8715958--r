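#' Construct a brain volume container
#'
#' A minimal 3-D intensity grid with voxel size and a boolean brain mask.
#'
#' @param data 3-D numeric array of non-negative intensities.
#' @param voxel_mm Isotropic voxel size in millimetres.
#' @param mask Logical array of the same shape (defaults to all-TRUE).
#' @return Object of class `brain_volume`.
#' @export
brain_volume <- function(data, voxel_mm = 2, mask = NULL) {
  if (length(dim(data)) != 3L) {
    stop_petriage("`data` must be a 3-D array.", "petriage_shape_error")
  }
  if (is.null(mask)) mask <- array(TRUE, dim(data))
  if (!identical(dim(mask), dim(data))) {
    stop_petriage("`mask` and `data` shapes differ.", "petriage_shape_error")
  }
  assert_scalar_number(voxel_mm, "voxel_mm", min = 1e-8)
  if (any(!is.finite(data[mask]))) {
    stop_petriage("non-finite intensities inside the mask.", "petriage_validation_error")
  }
  structure(list(data = data, voxel_mm = voxel_mm, mask = mask),
            class = "brain_volume")
}

#' @export
print.brain_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<brain_volume> %dx%dx%d, %.3g mm voxels, %d in-mask voxels\n",
              d[1], d[2], d[3], x$voxel_mm, sum(x$mask)))
  invisible(x)
}

# Severity of the AD-pattern metabolic effect for one sample.
.sample_severity <- function(group, true_state, mild_severity) {
  if (true_state == "healthy") return(0)
  if (group == "certain_impaired") return(1)
  mild_severity
}

#' Generate one phantom SUV volume
#'
#' Voxel intensity model:
#' `baseline * (1 - delta_ad * severity * [AD-pattern ROI]) *`
#' `(1 - delta_dep * [non-energetic] * [depression-pattern ROI]) + noise`,
#' with severity 1 for certain-impaired, `mild_severity` for
#' uncertain-impaired and 0 for healthy samples. Pons voxels are set to the
#' configured pons intensity before noise. Gaussian noise is added inside
#' the brain mask and the pons; the exterior stays exactly zero.
#'
#' @param sample One cohort row (a list or one-row tibble with `group`,
#'   `true_state`, `energetic`).
#' @param atlas A [build_atlas()] result on the configured grid.
#' @param config A [generator_config()].
#' @param seed Integer seed for this volume's noise.
#' @return A [brain_volume()] whose mask is the atlas brain mask.
#' @export
generate_volume <- function(sample, atlas, config = generator_config(), seed = 1L) {
  vp <- config$volume_params
  if (atlas$grid_edge != vp$grid_edge) {
    stop_petriage("atlas grid does not match the configured grid edge.",
                  "petriage_shape_error")
  }
  sev <- .sample_severity(sample$group, sample$true_state, config$mild_severity)
  nonenergetic <- !isTRUE(sample$energetic == TRUE || sample$energetic == 1)

  lab <- atlas$labels
  ad_mask <- lab %in% atlas$names[ad_pattern_rois()]
  dep_mask <- lab %in% atlas$names[depression_pattern_rois()]
  pons_mask <- lab == atlas$names[["pons"]]

  v <- ifelse(atlas$brain_mask, vp$baseline, 0)
  v <- v * (1 - vp$delta_ad * sev * ad_mask)
  v <- v * (1 - vp$delta_dep * as.numeric(nonenergetic) * dep_mask)
  v[pons_mask] <- vp$pons

  if (vp$noise_sd > 0) {
    noisy <- atlas$brain_mask | pons_mask
    v[noisy] <- with_seed(seed, v[noisy] + stats::rnorm(sum(noisy), 0, vp$noise_sd))
  }
  dim(v) <- dim(lab)
  brain_volume(v, voxel_mm = vp$voxel_mm, mask = atlas$brain_mask)
}

#' Generate phantom volumes for a whole cohort
#'
#' One volume per cohort row; each volume's noise seed is derived
#' deterministically from `config$seed` and the row index.
#'
#' @inheritParams generate_volume
#' @param cohort Cohort tibble.
#' @return Named list of [brain_volume()] objects (names = sample ids).
#' @export
generate_volumes <- function(cohort, atlas, config = generator_config()) {
  out <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    out[[i]] <- generate_volume(cohort[i, ], atlas, config,
                                seed = config$seed * 100003L %% 2147483L + i)
  }
  stats::setNames(out, cohort$id)
}
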