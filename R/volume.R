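#' PET volume container
#'
#' A `pet_volume` carries a 3D grid of voxel intensities in SUV units plus
#' its physical geometry. The coordinate convention is voxel-centred and
#' 0-based: the physical position of voxel index `(i, j, k)` is
#' `origin_mm + c(i, j, k) * spacing_mm`, with axis 3 the axial (z)
#' direction.
#'
#' @param intensities Numeric 3D array of non-negative, finite SUV values.
#' @param spacing_mm Numeric length-3 vector of strictly positive voxel
#'   sides in mm.
#' @param origin_mm Numeric length-3 physical position of voxel (0,0,0).
#' @param subject_id Optional subject identifier.
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(intensities, spacing_mm, origin_mm = c(0, 0, 0),
                       subject_id = NA_character_) {
  stopifnot(is.array(intensities), length(dim(intensities)) == 3L)
  if (!all(is.finite(intensities)))
    stop("pet_volume: intensities must be finite")
  if (any(intensities < 0))
    stop("pet_volume: intensities must be non-negative (SUV)")
  spacing_mm <- as.numeric(spacing_mm)
  stopifnot(length(spacing_mm) == 3L, all(spacing_mm > 0))
  origin_mm <- as.numeric(origin_mm)
  stopifnot(length(origin_mm) == 3L, all(is.finite(origin_mm)))
  structure(
    list(intensities = intensities, spacing_mm = spacing_mm,
         origin_mm = origin_mm, subject_id = subject_id),
    class = "pet_volume"
  )
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<pet_volume %s: %d x %d x %d voxels, spacing (%g, %g, %g) mm, SUV range [%.3g, %.3g]>\n",
    x$subject_id, d[1], d[2], d[3],
    x$spacing_mm[1], x$spacing_mm[2], x$spacing_mm[3],
    min(x$intensities), max(x$intensities)))
  invisible(x)
}

#' Nodule annotation
#'
#' Records the reference-standard annotation of a single solid pulmonary
#' nodule: its physical centre, its average diameter on CT, and its class.
#' The eligibility range for indeterminate solid nodules is a diameter in
#' (8, 30] mm.
#'
#' @param center_mm Numeric length-3 physical centre of the nodule.
#' @param diameter_mm Nodule average diameter in mm, in (8, 30].
#' @param label `"benign"` or `"malignant"`.
#' @return An object of class `nodule_annotation`.
#' @export
nodule_annotation <- function(center_mm, diameter_mm, label) {
  center_mm <- as.numeric(center_mm)
  stopifnot(length(center_mm) == 3L, all(is.finite(center_mm)),
            length(diameter_mm) == 1L, is.finite(diameter_mm))
  if (diameter_mm <= 8 || diameter_mm > 30)
    stop("nodule_annotation: diameter must lie in (8, 30] mm (eligibility range)")
  label <- as.character(as_nodule_label(label))
  structure(list(center_mm = center_mm, diameter_mm = diameter_mm,
                 label = label),
            class = "nodule_annotation")
}

# Physical position of every voxel along one axis.
axis_positions <- function(volume, axis) {
  n <- dim(volume$intensities)[axis]
  volume$origin_mm[axis] + (seq_len(n) - 1) * volume$spacing_mm[axis]
}

# TRUE if a physical point lies within the voxel-centre bounding box.
point_in_volume <- function(volume, point_mm) {
  d <- dim(volume$intensities)
  lo <- volume$origin_mm
  hi <- volume$origin_mm + (d - 1) * volume$spacing_mm
  all(point_mm >= lo - 1e-9) && all(point_mm <= hi + 1e-9)
}

#' Maximum standardised uptake value within an annotated nodule
#'
#' Returns the maximum voxel intensity inside the sphere of the annotated
#' diameter centred at the annotated nodule centre: the conventional SUVmax
#' biomarker the CNN is compared against.
#'
#' @param volume A [pet_volume].
#' @param annotation A [nodule_annotation] whose centre lies inside the
#'   volume.
#' @return The maximum SUV within the nodule sphere.
#' @export
suvmax_score <- function(volume, annotation) {
  stopifnot(inherits(volume, "pet_volume"),
            inherits(annotation, "nodule_annotation"))
  if (!point_in_volume(volume, annotation$center_mm))
    stop("suvmax_score: annotation centre lies outside the volume")
  r <- annotation$diameter_mm / 2
  px <- axis_positions(volume, 1) - annotation$center_mm[1]
  py <- axis_positions(volume, 2) - annotation$center_mm[2]
  pz <- axis_positions(volume, 3) - annotation$center_mm[3]
  d <- dim(volume$intensities)
  dist2 <- outer(outer(px^2, py^2, "+"), pz^2, "+")
  mask <- dist2 <= r^2 + 1e-9
  if (!any(mask))
    stop("suvmax_score: the nodule sphere contains no voxel centre")
  max(volume$intensities[mask])
}
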