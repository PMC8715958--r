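#' Region names used by the geometric phantom atlas
#'
#' `ad_pattern_rois()` returns the regions carrying the Alzheimer-type
#' hypometabolism effect (temporoparietal / posterior-midline / mesial
#' temporal / frontal); `depression_pattern_rois()` returns the regions
#' carrying the depression-type effect (orbitofrontal-limbic circuit).
#' The two sets intersect in the mesial temporal regions.
#'
#' @return Character vector of region names.
#' @export
ad_pattern_rois <- function() {
  c("precuneus", "inferior_temporal", "posterior_cingulate", "hippocampus",
    "parahippocampus", "angular", "middle_cingulate", "frontal")
}

#' @rdname ad_pattern_rois
#' @export
depression_pattern_rois <- function() {
  c("medial_orbitofrontal", "anterior_cingulate", "insula", "hippocampus",
    "parahippocampus")
}

#' @rdname ad_pattern_rois
#' @export
atlas_roi_names <- function() {
  c("pons", "precuneus", "inferior_temporal", "posterior_cingulate",
    "hippocampus", "parahippocampus", "medial_orbitofrontal",
    "anterior_cingulate", "insula", "angular", "middle_cingulate",
    "frontal", "cerebellum")
}

# Fractional sphere layout (offsets from the grid centre, in units of the
# grid edge). Chosen so all cerebral spheres sit inside the brain ellipsoid,
# pairwise separations exceed twice the sphere radius, and the pons lies
# below the ellipsoid (outside the cerebral brain mask), mimicking its role
# as an extra-cerebral reference region.
.atlas_layout <- function() {
  list(
    ellipsoid_semiaxes = c(0.40, 0.44, 0.32),
    roi_radius = 0.07,
    pons_radius = 0.06,
    centers = rbind(
      frontal              = c( 0.00,  0.26,  0.16),
      medial_orbitofrontal = c( 0.00,  0.30, -0.04),
      anterior_cingulate   = c( 0.00,  0.12,  0.06),
      middle_cingulate     = c( 0.00, -0.04,  0.18),
      posterior_cingulate  = c( 0.00, -0.16,  0.04),
      precuneus            = c( 0.00, -0.28,  0.14),
      angular              = c( 0.24, -0.22,  0.08),
      inferior_temporal    = c( 0.28,  0.06, -0.06),
      insula               = c(-0.24,  0.10,  0.00),
      hippocampus          = c( 0.15, -0.02, -0.14),
      parahippocampus      = c(-0.15, -0.04, -0.14),
      cerebellum           = c( 0.00, -0.22, -0.18),
      pons                 = c( 0.00,  0.05, -0.42)
    )
  )
}

#' Build the deterministic geometric ROI atlas
#'
#' Constructs a phantom "brain": an ellipsoidal brain mask containing twelve
#' disjoint spherical cerebral regions, plus a pons sphere placed below the
#' ellipsoid (the pons serves as the extra-cerebral reference region for
#' SUVr normalisation). Placement is purely geometric and deterministic:
#' identical arguments yield voxel-identical atlases.
#'
#' @param grid_edge Edge length of the cubic voxel grid (>= 16).
#' @param voxel_mm Isotropic voxel size in millimetres.
#' @return An object of class `roi_atlas`: a list with `labels` (3-D integer
#'   array, 0 = background), `names` (named integer vector mapping region
#'   name to label), `brain_mask` (logical array covering the cerebral
#'   ellipsoid), `voxel_mm` and `grid_edge`.
#' @examples
#' atlas <- build_atlas(32)
#' table(atlas$labels[atlas$labels > 0])
#' @export
build_atlas <- function(grid_edge, voxel_mm = 2) {
  if (!is.numeric(grid_edge) || length(grid_edge) != 1L || grid_edge < 16) {
    stop_petriage("`grid_edge` must be a single integer >= 16 (grid too small to fit all regions).",
                  "petriage_sizing_error")
  }
  grid_edge <- as.integer(grid_edge)
  assert_scalar_number(voxel_mm, "voxel_mm", min = 1e-8)

  lay <- .atlas_layout()
  n <- grid_edge
  c0 <- (n + 1) / 2
  co <- arrayInd(seq_len(n^3), c(n, n, n))
  x <- (co[, 1] - c0) / n; y <- (co[, 2] - c0) / n; z <- (co[, 3] - c0) / n

  semi <- lay$ellipsoid_semiaxes
  brain <- (x / semi[1])^2 + (y / semi[2])^2 + (z / semi[3])^2 <= 1

  labels <- integer(n^3)
  nm <- rownames(lay$centers)
  ids <- stats::setNames(seq_along(nm), nm)
  for (r in nm) {
    ctr <- lay$centers[r, ]
    rad <- if (r == "pons") lay$pons_radius else lay$roi_radius
    inside <- (x - ctr[1])^2 + (y - ctr[2])^2 + (z - ctr[3])^2 <= rad^2
    if (!any(inside)) {
      stop_petriage(sprintf("grid_edge %d too small: region '%s' is empty.", n, r),
                    "petriage_sizing_error")
    }
    if (any(labels[inside] != 0L)) {
      stop_petriage(sprintf("grid_edge %d too small: region '%s' overlaps another region.", n, r),
                    "petriage_sizing_error")
    }
    if (r != "pons" && !all(brain[inside])) {
      stop_petriage(sprintf("grid_edge %d too small: region '%s' leaves the brain mask.", n, r),
                    "petriage_sizing_error")
    }
    labels[inside] <- ids[[r]]
  }
  if (any(brain & labels == ids[["pons"]])) {
    stop_petriage("pons intersects the cerebral brain mask.", "petriage_sizing_error")
  }

  structure(
    list(
      labels = array(labels, c(n, n, n)),
      names = ids,
      brain_mask = array(brain, c(n, n, n)),
      voxel_mm = voxel_mm,
      grid_edge = n
    ),
    class = "roi_atlas"
  )
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat(sprintf("<roi_atlas> %d^3 grid, %.3g mm voxels, %d regions, %d brain-mask voxels\n",
              x$grid_edge, x$voxel_mm, length(x$names), sum(x$brain_mask)))
  invisible(x)
}

# Logical mask of one named region.
atlas_mask <- function(atlas, roi) {
  if (!roi %in% names(atlas$names)) {
    stop_petriage(sprintf("unknown region '%s'.", roi), "petriage_parameter_error")
  }
  atlas$labels == atlas$names[[roi]]
}
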