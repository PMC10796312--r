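# Trilinear interpolation of a 3D array at fractional 0-based voxel
# coordinates (N x 3 matrix). Coordinates are clamped to the grid (edge
# extension); used by isotropic resampling and heatmap upsampling.
trilinear_sample <- function(arr, coords) {
  d <- dim(arr)
  cx <- pmin(pmax(coords[, 1], 0), d[1] - 1)
  cy <- pmin(pmax(coords[, 2], 0), d[2] - 1)
  cz <- pmin(pmax(coords[, 3], 0), d[3] - 1)
  x0 <- floor(cx); y0 <- floor(cy); z0 <- floor(cz)
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  fx <- cx - x0; fy <- cy - y0; fz <- cz - z0
  at <- function(i, j, k) arr[1 + i + d[1] * (j + d[2] * k)]
  (1 - fz) * ((1 - fy) * ((1 - fx) * at(x0, y0, z0) + fx * at(x1, y0, z0)) +
              fy       * ((1 - fx) * at(x0, y1, z0) + fx * at(x1, y1, z0))) +
  fz       * ((1 - fy) * ((1 - fx) * at(x0, y0, z1) + fx * at(x1, y0, z1)) +
              fy       * ((1 - fx) * at(x0, y1, z1) + fx * at(x1, y1, z1)))
}

#' Resample a PET volume to isotropic spacing
#'
#' Resamples to `target_mm` isotropic voxels by trilinear interpolation in
#' physical coordinates (the voxel-centre convention of [pet_volume]). The
#' physical extent is preserved to within one voxel; the origin is kept.
#'
#' @param volume A [pet_volume].
#' @param target_mm Target isotropic voxel side in mm (default 1.5).
#' @return A [pet_volume] with spacing `c(target_mm, target_mm, target_mm)`.
#' @export
resample_isotropic <- function(volume, target_mm = 1.5) {
  stopifnot(inherits(volume, "pet_volume"), target_mm > 0)
  if (!all(is.finite(volume$intensities)))
    stop("resample_isotropic: non-finite input intensities")
  d <- dim(volume$intensities)
  extent <- (d - 1) * volume$spacing_mm
  od <- pmax(2L, as.integer(floor(extent / target_mm + 1e-9)) + 1L)
  # 0-based fractional source indices of each output voxel centre
  gx <- (seq_len(od[1]) - 1) * target_mm / volume$spacing_mm[1]
  gy <- (seq_len(od[2]) - 1) * target_mm / volume$spacing_mm[2]
  gz <- (seq_len(od[3]) - 1) * target_mm / volume$spacing_mm[3]
  coords <- cbind(rep(gx, times = od[2] * od[3]),
                  rep(rep(gy, each = od[1]), times = od[3]),
                  rep(gz, each = od[1] * od[2]))
  vals <- trilinear_sample(volume$intensities, coords)
  pet_volume(array(vals, dim = od), spacing_mm = rep(target_mm, 3),
             origin_mm = volume$origin_mm, subject_id = volume$subject_id)
}

#' Crop the fixed-size nodule-centred cube
#'
#' Extracts a cube of physical side `side_mm` (60 mm by default, twice the
#' maximum eligible nodule diameter) centred on the voxel nearest to
#' `center_mm`. At the default 1.5 mm isotropic spacing this yields the
#' 40 x 40 x 40 network input. For the even side length the centre voxel
#' sits at 0-based index `side/2` on each axis (upper-middle convention).
#' Regions falling outside the volume are zero-filled.
#'
#' @param volume A [pet_volume], normally already resampled to isotropic
#'   spacing.
#' @param center_mm Physical nodule centre (length-3), which must lie
#'   inside the volume.
#' @param side_mm Physical side length of the cube in mm.
#' @return A 3D numeric array of side `round(side_mm / spacing)` voxels,
#'   with attribute `subject_id`.
#' @export
crop_cube <- function(volume, center_mm, side_mm = 60) {
  stopifnot(inherits(volume, "pet_volume"), length(center_mm) == 3L)
  if (!point_in_volume(volume, center_mm))
    stop("crop_cube: centre lies outside the volume")
  sp <- volume$spacing_mm
  n <- as.integer(round(side_mm / sp))
  if (length(unique(n)) != 1L)
    stop("crop_cube: anisotropic spacing does not yield a cubic crop; ",
         "resample first")
  n <- n[1]
  d <- dim(volume$intensities)
  ci <- as.integer(round((center_mm - volume$origin_mm) / sp))
  start <- ci - n %/% 2                      # centre voxel lands at n %/% 2
  out <- array(0, dim = rep(n, 3))
  src_lo <- pmax(start, 0L)
  src_hi <- pmin(start + n - 1L, d - 1L)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo - start
    dst_hi <- src_hi - start
    out[(dst_lo[1] + 1):(dst_hi[1] + 1),
        (dst_lo[2] + 1):(dst_hi[2] + 1),
        (dst_lo[3] + 1):(dst_hi[3] + 1)] <-
      volume$intensities[(src_lo[1] + 1):(src_hi[1] + 1),
                         (src_lo[2] + 1):(src_hi[2] + 1),
                         (src_lo[3] + 1):(src_hi[3] + 1)]
  }
  attr(out, "subject_id") <- volume$subject_id
  out
}

#' Fit fold-level min-max normalisation statistics
#'
#' The statistics are global scalars over every voxel of every training
#' tensor of the fold (not per-volume), so inter-subject SUV contrast is
#' preserved. Validation and test tensors are normalised with the training
#' statistics of the respective fold.
#'
#' @param training A list of 3D arrays (or a single array): the fold's
#'   original (pre-augmentation) training tensors.
#' @param fold_id Optional fold identifier carried in the result.
#' @return An object of class `norm_stats` with fields `min_value`,
#'   `max_value`, `fold_id`.
#' @export
fit_minmax <- function(training, fold_id = NA_character_) {
  if (!is.list(training)) training <- list(training)
  if (length(training) == 0L) stop("fit_minmax: empty training list")
  mn <- min(vapply(training, min, numeric(1)))
  mx <- max(vapply(training, max, numeric(1)))
  if (!(mx > mn))
    stop("fit_minmax: degenerate statistics (max == min)")
  structure(list(min_value = mn, max_value = mx, fold_id = fold_id),
            class = "norm_stats")
}

#' Apply min-max normalisation
#'
#' Maps `v` to `(v - min) / (max - min)`. Training tensors land in [0, 1];
#' validation/test values may fall outside that range and are preserved
#' unless `clip = TRUE`.
#'
#' @param tensor A numeric array.
#' @param stats A `norm_stats` object from [fit_minmax].
#' @param clip If `TRUE`, clamp the result to [0, 1].
#' @return The normalised array (attributes preserved).
#' @export
apply_minmax <- function(tensor, stats, clip = FALSE) {
  stopifnot(inherits(stats, "norm_stats"))
  out <- (tensor - stats$min_value) / (stats$max_value - stats$min_value)
  if (clip) out[] <- pmin(pmax(out, 0), 1)
  out
}

#' Invert min-max normalisation
#'
#' @param tensor A normalised array.
#' @param stats The `norm_stats` used to normalise it.
#' @return The array on the original intensity scale.
#' @export
invert_minmax <- function(tensor, stats) {
  stopifnot(inherits(stats, "norm_stats"))
  tensor * (stats$max_value - stats$min_value) + stats$min_value
}

# Stack a list of equal-shape 3D tensors into the (d, h, w, C=1, B) block
# the network consumes.
stack_tensors <- function(tensors) {
  if (is.array(tensors) && length(dim(tensors)) == 5L) return(tensors)
  if (is.array(tensors) && length(dim(tensors)) == 3L)
    tensors <- list(tensors)
  if (length(tensors) == 0L) stop("stack_tensors: empty tensor list")
  d <- dim(tensors[[1]])
  arr <- array(0, dim = c(d, 1L, length(tensors)))
  for (i in seq_along(tensors)) arr[, , , 1L, i] <- tensors[[i]]
  arr
}
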