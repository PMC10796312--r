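#' Class-balanced offline augmentation plan
#'
#' Houses the per-class augmentation factors: counts of translated, rotated
#' and noise-injected copies of every original image. The defaults are the
#' study factors — minority class (malignant) 20 translations, 21 rotations
#' (7 per axis) and 20 noise copies (7, 7, 6 at noise sd 0.1, 0.3, 0.5);
#' majority class 16, 15 (5 per axis) and 16 (6, 5, 5) — which, applied to
#' a 41/49 minority/majority cohort, yield about 4900 images in total and
#' approximate class balance.
#'
#' @param minority,majority Per-class sub-plans: lists with
#'   `n_translations`, `n_rotations_per_axis`, and `noise_counts` (a named
#'   vector, one count per noise sd).
#' @param translation_range_vox Maximum absolute shift per axis, in voxels.
#' @param rotation_range_deg Maximum absolute rotation angle, in degrees.
#' @param noise_sd Noise standard deviations (on the normalised [0, 1]
#'   intensity scale) matching `noise_counts`.
#' @param seed Integer seed; per-subject draws are sub-seeded from it.
#' @return An object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(
    minority = list(n_translations = 20L, n_rotations_per_axis = 7L,
                    noise_counts = c(7L, 7L, 6L)),
    majority = list(n_translations = 16L, n_rotations_per_axis = 5L,
                    noise_counts = c(6L, 5L, 5L)),
    translation_range_vox = 10L,
    rotation_range_deg = 45,
    noise_sd = c(0.1, 0.3, 0.5),
    seed = 1L) {
  for (cls in list(minority, majority)) {
    stopifnot(cls$n_translations >= 0L, cls$n_rotations_per_axis >= 0L,
              length(cls$noise_counts) == length(noise_sd),
              all(cls$noise_counts >= 0L))
  }
  stopifnot(translation_range_vox >= 0L, rotation_range_deg >= 0,
            all(noise_sd > 0))
  structure(list(minority = minority, majority = majority,
                 translation_range_vox = as.integer(translation_range_vox),
                 rotation_range_deg = rotation_range_deg,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "augmentation_plan")
}

# Augmented copies per original for one class role.
class_augmentation_sum <- function(plan, role) {
  cls <- plan[[role]]
  cls$n_translations + 3L * cls$n_rotations_per_axis + sum(cls$noise_counts)
}

#' Closed-form size of an augmented dataset
#'
#' @param plan An [augmentation_plan].
#' @param n_minority,n_majority Original image counts per class role.
#' @return Total images (originals plus augmented copies).
#' @export
augmented_dataset_size <- function(plan, n_minority, n_majority) {
  n_minority * (1L + class_augmentation_sum(plan, "minority")) +
    n_majority * (1L + class_augmentation_sum(plan, "majority"))
}

#' Translate a tensor by an integer voxel shift
#'
#' Displaces the contents by `shift_vox`; vacated voxels are filled with
#' zero (the background value).
#'
#' @param tensor A 3D numeric array.
#' @param shift_vox Integer length-3 shift, each component within
#'   `[-max_shift, max_shift]`.
#' @param max_shift Allowed maximum absolute shift (10 voxels = 15 mm at
#'   1.5 mm spacing, chosen so a centred nodule is never moved out of the
#'   tensor).
#' @return The translated array.
#' @export
translate_tensor <- function(tensor, shift_vox, max_shift = 10L) {
  stopifnot(length(dim(tensor)) == 3L, length(shift_vox) == 3L)
  shift_vox <- as.integer(shift_vox)
  if (any(abs(shift_vox) > max_shift))
    stop("translate_tensor: |shift| exceeds ", max_shift, " voxels")
  d <- dim(tensor)
  out <- array(0, dim = d)
  src_lo <- pmax(1L - shift_vox, 1L)
  src_hi <- pmin(d - shift_vox, d)
  if (all(src_lo <= src_hi)) {
    dst_lo <- src_lo + shift_vox
    dst_hi <- src_hi + shift_vox
    out[dst_lo[1]:dst_hi[1], dst_lo[2]:dst_hi[2], dst_lo[3]:dst_hi[3]] <-
      tensor[src_lo[1]:src_hi[1], src_lo[2]:src_hi[2], src_lo[3]:src_hi[3]]
  }
  out
}

#' Rotate a tensor about a centre axis
#'
#' Applies a rotation about the axis through the tensor centre as the
#' composite transform translate-to-centre, rotate, translate-back.
#' Intensities are obtained by bilinear interpolation within each slice
#' perpendicular to the rotation axis; samples falling outside the grid are
#' zero (background fill).
#'
#' @param tensor A 3D numeric array.
#' @param axis `"x"`, `"y"` or `"z"` (axis 3 is axial).
#' @param angle_deg Rotation angle in degrees, within `[-max_angle,
#'   max_angle]`.
#' @param max_angle Allowed maximum absolute angle (degrees).
#' @return The rotated array.
#' @export
rotate_tensor <- function(tensor, axis = c("x", "y", "z"), angle_deg,
                          max_angle = 45) {
  axis <- match.arg(axis)
  stopifnot(length(dim(tensor)) == 3L, length(angle_deg) == 1L)
  if (abs(angle_deg) > max_angle)
    stop("rotate_tensor: |angle| exceeds ", max_angle, " degrees")
  d <- dim(tensor)
  plane <- switch(axis, x = c(2L, 3L), y = c(1L, 3L), z = c(1L, 2L))
  theta <- angle_deg * pi / 180
  # 0-based index grids of the full volume
  i1 <- rep(seq_len(d[1]) - 1, times = d[2] * d[3])
  i2 <- rep(rep(seq_len(d[2]) - 1, each = d[1]), times = d[3])
  i3 <- rep(seq_len(d[3]) - 1, each = d[1] * d[2])
  idx <- cbind(i1, i2, i3)
  c1 <- (d[plane[1]] - 1) / 2
  c2 <- (d[plane[2]] - 1) / 2
  u <- idx[, plane[1]] - c1
  v <- idx[, plane[2]] - c2
  # inverse mapping: source = R(-theta) (target - centre) + centre
  su <- cos(theta) * u + sin(theta) * v + c1
  sv <- -sin(theta) * u + cos(theta) * v + c2
  inside <- su >= 0 & su <= d[plane[1]] - 1 & sv >= 0 & sv <= d[plane[2]] - 1
  u0 <- floor(su); v0 <- floor(sv)
  fu <- su - u0; fv <- sv - v0
  clamp <- function(i, axis) pmin(pmax(i, 0), d[axis] - 1)
  u0c <- clamp(u0, plane[1]); u1c <- clamp(u0 + 1, plane[1])
  v0c <- clamp(v0, plane[2]); v1c <- clamp(v0 + 1, plane[2])
  src <- idx
  lin <- function(a, b) {
    src[, plane[1]] <- a; src[, plane[2]] <- b
    tensor[1 + src[, 1] + d[1] * (src[, 2] + d[2] * src[, 3])]
  }
  val <- (1 - fv) * ((1 - fu) * lin(u0c, v0c) + fu * lin(u1c, v0c)) +
         fv       * ((1 - fu) * lin(u0c, v1c) + fu * lin(u1c, v1c))
  val[!inside] <- 0
  array(val, dim = d)
}

#' Add i.i.d. Gaussian noise to a tensor
#'
#' @param tensor A numeric array.
#' @param sigma Noise standard deviation (on the tensor's intensity scale).
#' @param seed Optional local seed for a reproducible noise field.
#' @return `tensor + N(0, sigma^2)` per voxel.
#' @export
add_noise <- function(tensor, sigma, seed = NULL) {
  stopifnot(sigma >= 0)
  with_seed(seed, tensor + array(rnorm(length(tensor), 0, sigma),
                                 dim = dim(tensor)))
}

#' Augment one subject's tensor
#'
#' Produces the class-role's full complement of augmented copies: each
#' augmented example carries exactly one transform (a translation, a
#' single-axis rotation, or a noise injection). Translation shifts are
#' drawn independently per axis, uniform over the integer range; rotation
#' angles are uniform continuous within the range, excluding |angle| < 1
#' degree to avoid near-duplicates, evenly apportioned over the three axes.
#'
#' @param tensor A 3D numeric array (normalised network input).
#' @param class_role `"minority"` or `"majority"`.
#' @param plan An [augmentation_plan].
#' @param seed Optional local seed.
#' @return A list of augmented tensors; each has attribute `transform`
#'   describing the applied operation and its parameters.
#' @export
augment_subject <- function(tensor, class_role = c("minority", "majority"),
                            plan, seed = NULL) {
  class_role <- match.arg(class_role)
  stopifnot(inherits(plan, "augmentation_plan"))
  cls <- plan[[class_role]]
  with_seed(seed, {
    out <- list()
    r <- plan$translation_range_vox
    for (i in seq_len(cls$n_translations)) {
      repeat {
        shift <- sample(seq(-r, r), 3L, replace = TRUE)
        if (any(shift != 0L)) break
      }
      t <- translate_tensor(tensor, shift, max_shift = r)
      attr(t, "transform") <- list(type = "translation", shift_vox = shift)
      out[[length(out) + 1L]] <- t
    }
    for (axis in c("x", "y", "z")) {
      for (i in seq_len(cls$n_rotations_per_axis)) {
        repeat {
          ang <- runif(1, -plan$rotation_range_deg, plan$rotation_range_deg)
          if (abs(ang) >= 1) break
        }
        t <- rotate_tensor(tensor, axis, ang,
                           max_angle = plan$rotation_range_deg)
        attr(t, "transform") <- list(type = "rotation", axis = axis,
                                     angle_deg = ang)
        out[[length(out) + 1L]] <- t
      }
    }
    for (si in seq_along(plan$noise_sd)) {
      for (i in seq_len(cls$noise_counts[si])) {
        t <- add_noise(tensor, plan$noise_sd[si])
        attr(t, "transform") <- list(type = "noise",
                                     sigma = plan$noise_sd[si])
        out[[length(out) + 1L]] <- t
      }
    }
    out
  })
}

#' Build the augmented dataset for a set of labelled originals
#'
#' The minority class role is assigned to the rarer label (the malignant
#' class in the study cohort; ties go to malignant). The returned dataset
#' is the originals followed by every augmented copy; labels are preserved
#' under augmentation. Per-subject draws are sub-seeded from the plan seed
#' and the subject identifier, so the dataset is reproducible
#' subject-by-subject.
#'
#' @param tensors A named list of 3D arrays (names are subject ids; unnamed
#'   lists are given positional ids).
#' @param labels Benign/malignant labels aligned with `tensors`.
#' @param plan An [augmentation_plan].
#' @return A list with `tensors` (list of arrays), `labels` (factor),
#'   `is_augmented` (logical), `subject_id` (character), and `provenance`
#'   (data frame of applied transforms).
#' @export
build_augmented_dataset <- function(tensors, labels, plan) {
  stopifnot(inherits(plan, "augmentation_plan"),
            length(tensors) == length(labels))
  labels <- as_nodule_label(labels)
  if (is.null(names(tensors)))
    names(tensors) <- sprintf("S%03d", seq_along(tensors))
  if (length(tensors) == 0L)
    return(list(tensors = list(), labels = labels,
                is_augmented = logical(0), subject_id = character(0),
                provenance = data.frame()))
  counts <- table(labels)
  # rarer label takes the minority role (ties to malignant, the study's
  # minority class); with a single-class input the study roles apply
  minority_label <- if (counts[["benign"]] == 0L ||
                        counts[["malignant"]] <= counts[["benign"]])
    "malignant" else "benign"
  out_t <- list(); out_l <- character(0); out_a <- logical(0)
  out_s <- character(0); prov <- list()
  for (i in seq_along(tensors)) {
    id <- names(tensors)[i]
    lab <- as.character(labels[i])
    role <- if (lab == minority_label) "minority" else "majority"
    out_t[[length(out_t) + 1L]] <- tensors[[i]]
    out_l <- c(out_l, lab); out_a <- c(out_a, FALSE); out_s <- c(out_s, id)
    prov[[length(prov) + 1L]] <- data.frame(
      subject_id = id, type = "original", detail = "", stringsAsFactors = FALSE)
    augs <- augment_subject(tensors[[i]], role, plan,
                            seed = sub_seed(plan$seed, id))
    for (a in augs) {
      tr <- attr(a, "transform")
      out_t[[length(out_t) + 1L]] <- a
      out_l <- c(out_l, lab); out_a <- c(out_a, TRUE); out_s <- c(out_s, id)
      prov[[length(prov) + 1L]] <- data.frame(
        subject_id = id, type = tr$type,
        detail = paste(names(tr)[-1], unlist(tr[-1]), sep = "=",
                       collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(tensors = out_t, labels = as_nodule_label(out_l),
       is_augmented = out_a, subject_id = out_s,
       provenance = do.call(rbind, prov))
}
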