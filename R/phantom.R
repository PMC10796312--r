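#' Specification of a phantom PET cohort
#'
#' Defines the statistical structure of a simulated cohort of solid
#' pulmonary nodules imaged with 2-[18F]FDG PET. Defaults reproduce the
#' study conditions the pipeline assumes: 113 subjects with 45.1% malignant
#' prevalence, nodule diameters log-normal with median 13 mm and IQR 5 mm
#' truncated to the (8, 30] mm eligibility range, and malignant nodules
#' showing higher nodule-to-background uptake contrast than benign ones
#' with overlap between the classes.
#'
#' Raw phantoms are generated at scanner-like anisotropic spacing
#' (`native_spacing_mm`), emulating multi-scanner acquisition; `voxel_mm`
#' is the isotropic spacing the preprocessing resamples to.
#'
#' @param n_subjects Number of subjects.
#' @param prevalence Malignant fraction, strictly in (0, 1).
#' @param diameter_median_mm,diameter_iqr_mm Median and interquartile range
#'   of the nodule diameter distribution (mm).
#' @param voxel_mm Target isotropic voxel side after resampling (mm).
#' @param field_mm Physical extent of the simulated volume per axis (mm).
#' @param native_spacing_mm Anisotropic voxel spacing of the raw phantom.
#' @param background_suv Background physiological uptake level (SUV).
#' @param contrast_malignant,contrast_benign Median nodule-to-background
#'   uptake ratio per class; must satisfy
#'   `contrast_malignant > contrast_benign >= 1`.
#' @param contrast_sd Log-scale dispersion of the contrast draw.
#' @param psf_fwhm_mm Full width at half maximum of the Gaussian
#'   point-spread blur (mm), emulating PET spatial resolution.
#' @param n_distractors Number of peripheral background hot spots.
#' @param noise_sd Additive Gaussian noise scale (SUV), truncated at zero.
#' @param center_jitter_mm Maximum offset of the nodule centre from the
#'   volume centre per axis (mm).
#' @param seed Integer seed of the cohort.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_subjects = 113,
                         prevalence = 0.451,
                         diameter_median_mm = 13,
                         diameter_iqr_mm = 5,
                         voxel_mm = 1.5,
                         field_mm = c(90, 90, 90),
                         native_spacing_mm = c(2, 2, 3),
                         background_suv = 1.0,
                         contrast_malignant = 4.0,
                         contrast_benign = 1.5,
                         contrast_sd = 0.35,
                         psf_fwhm_mm = 6,
                         n_distractors = 2,
                         noise_sd = 0.1,
                         center_jitter_mm = 3,
                         seed = 20230830) {
  spec <- structure(as.list(environment()), class = "phantom_spec")
  validate_phantom_spec(spec)
}

validate_phantom_spec <- function(spec) {
  stopifnot(spec$n_subjects >= 1,
            spec$diameter_median_mm > 0, spec$diameter_iqr_mm > 0,
            spec$voxel_mm > 0, all(spec$native_spacing_mm > 0),
            length(spec$field_mm) == 3L, all(spec$field_mm > 0),
            spec$background_suv > 0, spec$contrast_sd >= 0,
            spec$psf_fwhm_mm >= 0, spec$n_distractors >= 0,
            spec$noise_sd >= 0, spec$center_jitter_mm >= 0)
  if (spec$prevalence <= 0 || spec$prevalence >= 1)
    stop("phantom_spec: prevalence must lie strictly in (0, 1)")
  if (!(spec$contrast_malignant > spec$contrast_benign))
    stop("phantom_spec: contrast_malignant must exceed contrast_benign")
  if (spec$contrast_benign < 1)
    stop("phantom_spec: contrast_benign must be >= 1")
  spec
}

# Log-normal sdlog reproducing the requested median/IQR:
# IQR = 2 * median * sinh(qnorm(0.75) * sdlog).
diameter_sdlog <- function(median_mm, iqr_mm) {
  asinh(iqr_mm / (2 * median_mm)) / qnorm(0.75)
}

# One truncated log-normal diameter draw in (8, 30] mm.
draw_diameter <- function(spec) {
  mu <- log(spec$diameter_median_mm)
  sdl <- diameter_sdlog(spec$diameter_median_mm, spec$diameter_iqr_mm)
  for (i in seq_len(1000L)) {
    d <- exp(rnorm(1L, mu, sdl))
    if (d > 8 && d <= 30) return(d)
  }
  stop("draw_diameter: truncation bounds rejected 1000 draws; check spec")
}

# Separable Gaussian blur with per-axis sigma in voxels; kernel truncated
# at 3 sigma and renormalised at the edges (band-matrix multiplication).
gaussian_blur3 <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 1e-8) next
    n <- d[axis]
    r <- max(1L, ceiling(3 * s))
    kern <- exp(-(seq(-r, r))^2 / (2 * s^2))
    band <- matrix(0, n, n)
    for (j in seq(-r, r)) {
      idx <- seq_len(n)
      src <- idx + j
      ok <- src >= 1 & src <= n
      band[cbind(idx[ok], src[ok])] <- band[cbind(idx[ok], src[ok])] +
        kern[j + r + 1]
    }
    band <- band / rowSums(band)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = n)
    m <- band %*% m
    arr <- aperm(array(m, dim = d[perm]), order(perm))
  }
  arr
}

#' Generate a single phantom PET volume with one nodule
#'
#' Builds a raw anisotropic PET volume containing uniform background
#' physiological uptake, one ellipsoidal nodule near the volume centre whose
#' plateau uptake is `background_suv` times a class-conditional contrast
#' draw, optional peripheral hot spots, a Gaussian point-spread blur, and
#' additive Gaussian noise truncated at zero.
#'
#' @param spec A [phantom_spec].
#' @param label `"benign"` or `"malignant"`.
#' @param subject_id Identifier stored in the volume and annotation.
#' @param seed Optional integer seed; if supplied the draw is reproducible
#'   independently of the surrounding RNG state.
#' @return A list with elements `volume` ([pet_volume]) and `annotation`
#'   ([nodule_annotation]).
#' @export
generate_phantom <- function(spec, label, subject_id = "S000", seed = NULL) {
  validate_phantom_spec(spec)
  label <- as.character(as_nodule_label(label))
  with_seed(seed, {
    sp <- spec$native_spacing_mm
    dims <- pmax(2L, as.integer(round(spec$field_mm / sp)))
    centre <- (dims - 1) / 2 * sp
    nod_centre <- centre + runif(3, -spec$center_jitter_mm,
                                 spec$center_jitter_mm)
    diameter <- draw_diameter(spec)
    if (diameter >= min(spec$field_mm))
      stop("generate_phantom: nodule diameter exceeds the field extent")
    radii <- diameter / 2 * runif(3, 0.8, 1.2)

    base <- if (label == "malignant") spec$contrast_malignant else
      spec$contrast_benign
    contrast <- max(1, base * exp(rnorm(1L, 0, spec$contrast_sd)))

    px <- (seq_len(dims[1]) - 1) * sp[1]
    py <- (seq_len(dims[2]) - 1) * sp[2]
    pz <- (seq_len(dims[3]) - 1) * sp[3]
    img <- array(spec$background_suv, dim = dims)

    inside <- outer(outer(((px - nod_centre[1]) / radii[1])^2,
                          ((py - nod_centre[2]) / radii[2])^2, "+"),
                    ((pz - nod_centre[3]) / radii[3])^2, "+") <= 1
    img[inside] <- spec$background_suv * contrast

    if (spec$n_distractors > 0) {
      for (i in seq_len(spec$n_distractors)) {
        # peripheral: at least 35% of the smallest field extent from centre
        repeat {
          pos <- runif(3, 0, (dims - 1) * sp)
          if (sqrt(sum((pos - centre)^2)) >= 0.35 * min(spec$field_mm)) break
        }
        rad <- runif(1, 4, 8)
        lev <- spec$background_suv * runif(1, 1.5, 3)
        blob <- outer(outer((px - pos[1])^2, (py - pos[2])^2, "+"),
                      (pz - pos[3])^2, "+") <= rad^2
        img[blob] <- pmax(img[blob], lev)
      }
    }

    if (spec$psf_fwhm_mm > 0) {
      sigma_mm <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2)))
      img <- gaussian_blur3(img, sigma_mm / sp)
    }
    if (spec$noise_sd > 0)
      img <- img + rnorm(length(img), 0, spec$noise_sd)
    img <- array(pmax(img, 0), dim = dims)

    list(volume = pet_volume(img, spacing_mm = sp, origin_mm = c(0, 0, 0),
                             subject_id = subject_id),
         annotation = nodule_annotation(nod_centre, diameter, label))
  })
}

#' Generate a phantom cohort on disk
#'
#' Draws class labels with exactly `round(n_subjects * prevalence)`
#' malignant subjects, simulates one phantom per subject (each with a
#' deterministic sub-seed derived from the cohort seed and the subject id),
#' writes the volumes as NRRD files, and writes the manifest CSV.
#'
#' @param spec A [phantom_spec].
#' @param out_dir Writable output directory (created if missing).
#' @return The manifest, as returned by [read_manifest], invisibly the
#'   same table that was written to `manifest.csv` in `out_dir`.
#' @export
generate_cohort <- function(spec, out_dir) {
  validate_phantom_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("generate_cohort: cannot create output directory ", out_dir)
  labels <- cohort_labels(spec)
  ids <- sprintf("S%03d", seq_len(spec$n_subjects))
  rows <- vector("list", spec$n_subjects)
  for (i in seq_len(spec$n_subjects)) {
    ph <- generate_phantom(spec, labels[i], subject_id = ids[i],
                           seed = sub_seed(spec$seed, ids[i]))
    fn <- paste0(ids[i], ".nrrd")
    write_nrrd(ph$volume, file.path(out_dir, fn))
    rows[[i]] <- data.frame(
      subject_id = ids[i], path = fn, label = ph$annotation$label,
      center_x_mm = ph$annotation$center_mm[1],
      center_y_mm = ph$annotation$center_mm[2],
      center_z_mm = ph$annotation$center_mm[3],
      diameter_mm = ph$annotation$diameter_mm,
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  read_manifest(file.path(out_dir, "manifest.csv"))
}

# Deterministic label sequence: exact class counts, seeded arrangement.
cohort_labels <- function(spec) {
  n_mal <- round(spec$n_subjects * spec$prevalence)
  labels <- c(rep("malignant", n_mal),
              rep("benign", spec$n_subjects - n_mal))
  with_seed(sub_seed(spec$seed, "labels"), sample(labels))
}
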