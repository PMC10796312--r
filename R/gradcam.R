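#' 3D Grad-CAM heatmap for one input tensor
#'
#' Gradient-weighted class activation mapping on the pre-sigmoid logit:
#' channel weights are the spatial average of the logit gradient at the
#' chosen convolutional layer, the map is the rectified weighted sum of
#' that layer's feature maps, trilinearly upsampled to the input grid and
#' max-normalised to [0, 1] (identically zero maps pass through).
#'
#' The default source layer is the deepest convolutional layer whose
#' output retains spatial extent of at least two voxels per axis: for the
#' stacked 3D CNN the last convolution collapses to a single voxel, whose
#' upsampled map would be uniform, so its penultimate convolution is used
#' instead.
#'
#' @param model A `trained_model`.
#' @param tensor A single input tensor (3D array matching the
#'   architecture's spatial input, normalised like the training data).
#' @param layer Id of a convolutional layer, or `NULL` for the default.
#' @return An object of class `gradcam_map`: `heatmap` (array of the input
#'   shape, values in [0, 1]), `layer`, `prob`.
#' @export
gradcam3d <- function(model, tensor, layer = NULL) {
  spec <- model$spec
  shapes <- spec$shapes
  conv_ids <- vapply(Filter(function(nd) nd$kind == "conv", spec$layers),
                     function(nd) nd$id, character(1))
  if (is.null(layer)) {
    roomy <- conv_ids[vapply(conv_ids,
                             function(id) min(shapes[[id]][1:3]) >= 2,
                             logical(1))]
    layer <- if (length(roomy)) tail(roomy, 1L) else tail(conv_ids, 1L)
  }
  if (!layer %in% conv_ids)
    stop("gradcam3d: layer '", layer, "' is not a convolutional layer")
  x <- stack_tensors(list(tensor))
  fwd <- forward_pass(spec, model$params, x, keep_cache = TRUE)
  bk <- backward_pass(spec, model$params, fwd, dlogit = 1, capture = layer)
  feat <- fwd$acts[[layer]]                      # (d, h, w, B = 1, C)
  grad <- bk$captured
  d <- dim(feat)
  nsp <- prod(d[1:3])
  w <- colMeans(matrix(grad, nrow = nsp, ncol = d[5]))
  cam <- matrix(feat, nrow = nsp, ncol = d[5]) %*% w
  cam <- pmax(array(cam, dim = d[1:3]), 0)
  up <- upsample_trilinear(cam, dim(tensor))
  mx <- max(up)
  if (mx > 0) up <- up / mx
  structure(list(heatmap = up, layer = layer,
                 prob = sigmoid(fwd$logits[1])),
            class = "gradcam_map")
}

# Trilinear upsampling of a 3D array to a target shape (align-corners
# grid mapping).
upsample_trilinear <- function(arr, target_dim) {
  d <- dim(arr)
  g <- lapply(1:3, function(a) {
    if (target_dim[a] == 1L) 0 else
      (seq_len(target_dim[a]) - 1) * (d[a] - 1) / (target_dim[a] - 1)
  })
  coords <- cbind(rep(g[[1]], times = target_dim[2] * target_dim[3]),
                  rep(rep(g[[2]], each = target_dim[1]),
                      times = target_dim[3]),
                  rep(g[[3]], each = target_dim[1] * target_dim[2]))
  array(trilinear_sample(arr, coords), dim = target_dim)
}

#' Thick axial slices
#'
#' Reformats a volume into `n_out` axial slices, each the mean of the
#' corresponding group of consecutive axial slices (40 -> 10 averages
#' groups of 4), for compact display.
#'
#' @param volume A 3D array whose axial (third) dimension is divisible by
#'   `n_out`.
#' @param n_out Number of output slices.
#' @return A list of `n_out` matrices.
#' @export
thick_slices <- function(volume, n_out = 10L) {
  stopifnot(length(dim(volume)) == 3L)
  nz <- dim(volume)[3]
  if (nz %% n_out != 0L)
    stop("thick_slices: axial size ", nz, " is not divisible by ", n_out)
  g <- nz %/% n_out
  lapply(seq_len(n_out), function(i) {
    idx <- ((i - 1L) * g + 1L):(i * g)
    apply(volume[, , idx, drop = FALSE], c(1, 2), mean)
  })
}

# Red-dominant colour ramp for heatmap overlays (low: black/transparent
# dark red, high: bright red).
heat_rgb <- function(v) {
  r <- pmin(1, 2 * v)
  g <- pmax(0, 1.2 * v - 0.55)
  b <- pmax(0, 0.8 * v - 0.6)
  list(r = r, g = g, b = b)
}

#' Fuse a PET slice with a Grad-CAM heatmap slice
#'
#' Renders the PET slice in grayscale and blends the heatmap on top in a
#' red-dominant colour map with opacity `alpha` scaled by the local
#' heatmap score, so zero-score regions show pure PET at any alpha.
#'
#' @param pet_slice Matrix of PET intensities (any scale; rescaled to
#'   [0, 1] for display).
#' @param heatmap_slice Matrix of Grad-CAM scores in [0, 1], same shape.
#' @param alpha Overlay opacity in [0, 1].
#' @return An array (nrow, ncol, 3) of RGB values in [0, 1].
#' @export
overlay <- function(pet_slice, heatmap_slice, alpha = 0.5) {
  if (!all(dim(pet_slice) == dim(heatmap_slice)))
    stop("overlay: slice shapes differ")
  stopifnot(alpha >= 0, alpha <= 1)
  rng <- range(pet_slice)
  gray <- if (diff(rng) > 0) (pet_slice - rng[1]) / diff(rng) else
    pet_slice * 0
  hm <- pmin(pmax(heatmap_slice, 0), 1)
  col <- heat_rgb(hm)
  a <- alpha * hm
  out <- array(0, dim = c(dim(pet_slice), 3))
  out[, , 1] <- (1 - a) * gray + a * col$r
  out[, , 2] <- (1 - a) * gray + a * col$g
  out[, , 3] <- (1 - a) * gray + a * col$b
  out
}

#' Grad-CAM gallery for an ensemble: four model rows by ten thick slices
#'
#' Builds the fusion-overlay gallery of one test volume: the top row shows
#' the thick-sliced PET input, followed by one row per fold model showing
#' the PET fused with that model's Grad-CAM heatmap.
#'
#' @param ensemble An `ensemble_model`.
#' @param tensor The raw (un-normalised) input tensor.
#' @param path Output PNG path.
#' @param n_slices Number of thick slices per row.
#' @param alpha Overlay opacity.
#' @return `path`, invisibly.
#' @export
gradcam_gallery <- function(ensemble, tensor, path, n_slices = 10L,
                            alpha = 0.5) {
  pet_rows <- thick_slices(tensor, n_slices)
  rows <- list(lapply(pet_rows, function(s) overlay(s, s * 0, 0)))
  for (k in seq_along(ensemble$fold_models)) {
    xk <- apply_minmax(tensor, ensemble$fold_stats[[k]])
    cam <- gradcam3d(ensemble$fold_models[[k]], xk)
    hm <- thick_slices(cam$heatmap, n_slices)
    rows[[k + 1L]] <- lapply(seq_len(n_slices), function(i)
      overlay(pet_rows[[i]], hm[[i]], alpha))
  }
  nr <- dim(tensor)[1]; nc <- dim(tensor)[2]
  img <- array(0, dim = c(nr * length(rows), nc * n_slices, 3))
  for (r in seq_along(rows)) {
    for (s in seq_len(n_slices)) {
      img[((r - 1) * nr + 1):(r * nr),
          ((s - 1) * nc + 1):(s * nc), ] <- rows[[r]][[s]]
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
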