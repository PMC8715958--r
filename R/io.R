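#' Read and write cohort and visit tables
#'
#' Plain CSV with the documented column headers; round-trips the tibbles
#' produced by [generate_cohort()] and [generate_longitudinal()].
#'
#' @param cohort,visits Tibble to write.
#' @param path File path.
#' @return The tibble (readers) or the path, invisibly (writers).
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  class(out) <- c("petriage_cohort", class(out))
  out
}

#' @rdname write_cohort
#' @export
write_visits <- function(visits, path) {
  readr::write_csv(visits, path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_visits <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Read and write volumes as NIfTI-1
#'
#' The voxel size is carried in the NIfTI header; the mask, when written,
#' travels as a companion `<path>_mask.nii.gz`.
#'
#' @param volume A [brain_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param with_mask Also write the companion mask file.
#' @export
write_volume <- function(volume, path, with_mask = TRUE) {
  RNifti::writeNifti(.as_nifti(volume$data, volume$voxel_mm), path)
  if (with_mask) {
    RNifti::writeNifti(
      .as_nifti(array(as.integer(volume$mask), dim(volume$mask)), volume$voxel_mm),
      sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
    )
  }
  invisible(path)
}

.as_nifti <- function(data, voxel_mm) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- rep(voxel_mm, 3)
  img
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  voxel_mm <- RNifti::pixdim(img)[1]
  mask_path <- sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  mask <- if (file.exists(mask_path)) {
    array(as.array(RNifti::readNifti(mask_path)) > 0, dim(img))
  } else {
    NULL
  }
  brain_volume(array(as.array(img), dim(img)), voxel_mm = voxel_mm, mask = mask)
}

#' Read and write the ROI atlas
#'
#' Labels as integer NIfTI-1 plus a JSON name map (`<path>.json`).
#'
#' @param atlas A [build_atlas()] result.
#' @param path Output path for the label image.
#' @export
write_atlas <- function(atlas, path) {
  RNifti::writeNifti(.as_nifti(atlas$labels, atlas$voxel_mm), path)
  jsonlite::write_json(as.list(atlas$names), paste0(path, ".json"), auto_unbox = TRUE)
  RNifti::writeNifti(
    .as_nifti(array(as.integer(atlas$brain_mask), dim(atlas$brain_mask)),
              atlas$voxel_mm),
    sub("(\\.nii(\\.gz)?)$", "_mask\\1", path)
  )
  invisible(path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(path) {
  img <- RNifti::readNifti(path)
  names <- unlist(jsonlite::read_json(paste0(path, ".json")))
  mask <- as.array(RNifti::readNifti(sub("(\\.nii(\\.gz)?)$", "_mask\\1", path))) > 0
  structure(
    list(labels = array(as.integer(as.array(img)), dim(img)),
         names = stats::setNames(as.integer(names), names(names)),
         brain_mask = array(mask, dim(img)),
         voxel_mm = RNifti::pixdim(img)[1],
         grid_edge = dim(img)[1]),
    class = "roi_atlas"
  )
}

#' Read and write a generator configuration as YAML
#'
#' @param config A [generator_config()].
#' @param path YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(list(
    n_samples = config$n_samples,
    group_proportions = as.list(config$group_proportions),
    score_params = as.data.frame(config$score_params),
    demo_params = as.data.frame(config$demo_params),
    slope_ranges = config$slope_ranges,
    decline_rates = lapply(config$decline_rates, as.list),
    visit_noise = as.list(config$visit_noise),
    nonenergetic_noise_factor = config$nonenergetic_noise_factor,
    gds_energy_props = as.list(config$gds_energy_props),
    gds_memory_props = as.list(config$gds_memory_props),
    gds_other_prop = config$gds_other_prop,
    mild_severity = config$mild_severity,
    volume_params = config$volume_params,
    seed = config$seed
  ), path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  generator_config(
    n_samples = y$n_samples,
    group_proportions = unlist(y$group_proportions),
    score_params = tibble::as_tibble(as.data.frame(y$score_params)),
    demo_params = tibble::as_tibble(as.data.frame(y$demo_params)),
    slope_ranges = lapply(y$slope_ranges, unlist),
    decline_rates = lapply(y$decline_rates, unlist),
    visit_noise = unlist(y$visit_noise),
    nonenergetic_noise_factor = y$nonenergetic_noise_factor,
    gds_energy_props = unlist(y$gds_energy_props),
    gds_memory_props = unlist(y$gds_memory_props),
    gds_other_prop = y$gds_other_prop,
    mild_severity = y$mild_severity,
    volume_params = y$volume_params,
    seed = y$seed
  )
}
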