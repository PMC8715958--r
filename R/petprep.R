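#' Normalise a SUV volume to SUVr by the pons mean
#'
#' Divides every voxel by the mean intensity over the pons reference
#' region, so the output pons mean is exactly 1. Scale-invariant:
#' `suv_to_suvr(c * v)` equals `suv_to_suvr(v)` for any `c > 0`.
#'
#' @param volume A [brain_volume()].
#' @param pons_mask Logical array (same shape) marking the pons.
#' @return The SUVr [brain_volume()].
#' @export
suv_to_suvr <- function(volume, pons_mask) {
  if (!identical(dim(pons_mask), dim(volume$data))) {
    stop_petriage("`pons_mask` shape differs from the volume.", "petriage_shape_error")
  }
  if (!any(pons_mask)) {
    stop_petriage("empty pons mask.", "petriage_normalization_error")
  }
  ref <- mean(volume$data[pons_mask])
  if (!is.finite(ref) || ref <= 0) {
    stop_petriage("pons mean is not positive; cannot normalise.",
                  "petriage_normalization_error")
  }
  volume$data <- volume$data / ref
  volume
}

# 1-D discrete Gaussian convolution matrix with reflect boundary.
# Column-stochastic, so the volume total is preserved.
.gauss_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {      # source column j spreads to reflected targets
    for (o in seq(-r, r)) {
      t <- j + o
      # half-sample symmetric reflection: 0 -> 1, -1 -> 2, n+1 -> n, ...
      while (t < 1L || t > n) {
        if (t < 1L) t <- 1L - t
        if (t > n) t <- 2L * n + 1L - t
      }
      K[t, j] <- K[t, j] + k[o + r + 1L]
    }
  }
  K
}

#' Smooth a volume with an isotropic Gaussian kernel
#'
#' Separable convolution with `sigma = fwhm / (2 sqrt(2 ln 2))` per axis
#' (converted to voxel units), reflect boundary handling. `fwhm_mm = 0` is
#' the identity. The kernel is normalised and the boundary reflective, so
#' the total intensity is preserved and constants are fixed points.
#'
#' @param volume A [brain_volume()].
#' @param fwhm_mm Full width at half maximum in millimetres (default 8).
#' @return The smoothed [brain_volume()].
#' @export
smooth_volume <- function(volume, fwhm_mm = 8) {
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm < 0) {
    stop_petriage("`fwhm_mm` must be a single number >= 0.", "petriage_parameter_error")
  }
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / volume$voxel_mm
  d <- dim(volume$data)
  a <- volume$data
  # axis 1
  K <- .gauss_conv_matrix(d[1], sigma_vox)
  a <- array(K %*% matrix(a, d[1], d[2] * d[3]), d)
  # axis 2
  K <- .gauss_conv_matrix(d[2], sigma_vox)
  a <- aperm(a, c(2, 1, 3))
  a <- array(K %*% matrix(a, d[2], d[1] * d[3]), c(d[2], d[1], d[3]))
  a <- aperm(a, c(2, 1, 3))
  # axis 3
  K <- .gauss_conv_matrix(d[3], sigma_vox)
  a <- aperm(a, c(3, 2, 1))
  a <- array(K %*% matrix(a, d[3], d[2] * d[1]), c(d[3], d[2], d[1]))
  a <- aperm(a, c(3, 2, 1))
  volume$data <- a
  volume
}

#' Extract the in-mask voxels as an aligned feature vector
#'
#' Values are taken in a fixed, documented scan order: ascending linear
#' index of the column-major array, i.e. x varies fastest, then y, then z
#' (lexicographic in (z, y, x)). The returned index map makes the mapping
#' invertible with [unmask()]; two volumes sharing a mask yield vectors
#' aligned element-wise by voxel.
#'
#' @param volume A [brain_volume()].
#' @param mask Logical array; defaults to the volume's own mask.
#' @return Object of class `masked_voxels`: list with `values`, `index`
#'   (linear indices) and `dim`.
#' @export
apply_mask <- function(volume, mask = NULL) {
  mask <- mask %||% volume$mask
  if (!identical(dim(mask), dim(volume$data))) {
    stop_petriage("mask shape differs from the volume.", "petriage_shape_error")
  }
  if (!any(mask)) stop_petriage("empty mask.", "petriage_masking_error")
  idx <- which(mask)
  structure(list(values = volume$data[idx], index = idx, dim = dim(volume$data)),
            class = "masked_voxels")
}

#' @rdname apply_mask
#' @param mv A `masked_voxels` object (optionally with replaced `values`).
#' @param fill Value for voxels outside the mask.
#' @export
unmask <- function(mv, fill = 0) {
  out <- array(fill, mv$dim)
  out[mv$index] <- mv$values
  out
}

# Stack a list of volumes sharing a mask into a voxel-by-sample matrix.
masked_matrix <- function(volumes, mask = NULL) {
  mask <- mask %||% volumes[[1]]$mask
  idx <- which(mask)
  vapply(volumes, function(v) v$data[idx], numeric(length(idx)))
}

#' Standard phantom preprocessing
#'
#' The default intensity pipeline applied to a generated SUV volume before
#' classification or voxel statistics: pons-reference SUVr normalisation,
#' then Gaussian smoothing (volumes are generated in template space, so no
#' spatial registration is involved).
#'
#' @param volume A [brain_volume()].
#' @param atlas The matching [build_atlas()] (provides the pons mask).
#' @param fwhm_mm Smoothing kernel FWHM in millimetres.
#' @return The preprocessed [brain_volume()].
#' @export
preprocess_volume <- function(volume, atlas, fwhm_mm = 8) {
  v <- suv_to_suvr(volume, atlas_mask(atlas, "pons"))
  smooth_volume(v, fwhm_mm)
}
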