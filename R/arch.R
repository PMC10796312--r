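# Declarative network definitions. An arch_spec is an ordered list of
# nodes forming a DAG (sequential for the stacked and VGG-like nets,
# branching for the inception-like net). Node kinds: input, conv, pool,
# flatten, dense, gap, concat. Convolutions and dense layers use LeakyReLU
# (alpha = 0.3) except the single output unit, whose sigmoid is applied at
# the loss/probability level.

node_conv <- function(id, input, filters, k = 3L, stride = 1L,
                      pad = "valid", activation = "leaky_relu") {
  list(id = id, kind = "conv", input = input, filters = as.integer(filters),
       k = as.integer(k), stride = as.integer(stride), pad = pad,
       activation = activation)
}
node_pool <- function(id, input, k = 2L, stride = 2L, pad = "valid") {
  list(id = id, kind = "pool", input = input, k = as.integer(k),
       stride = as.integer(stride), pad = pad)
}
node_dense <- function(id, input, units, activation = "leaky_relu") {
  list(id = id, kind = "dense", input = input, units = as.integer(units),
       activation = activation)
}
node_simple <- function(id, kind, input) list(id = id, kind = kind,
                                              input = input)

new_arch_spec <- function(family, layers, l2_lambda, leaky_alpha = 0.3,
                          input_shape = c(40L, 40L, 40L, 1L)) {
  spec <- structure(list(family = family, input_shape = input_shape,
                         layers = layers, leaky_alpha = leaky_alpha,
                         l2_lambda = l2_lambda),
                    class = "arch_spec")
  spec$shapes <- infer_shapes(spec)   # fail fast on inconsistent geometry
  spec
}

# Symmetric padding amounts per axis for "valid"/"same" (ceil division at
# same-padded layers, extra voxel on the trailing side).
pad_amounts <- function(n, k, stride, pad) {
  if (identical(pad, "valid")) return(c(0L, 0L))
  out <- ceiling(n / stride)
  total <- max((out - 1L) * stride + k - n, 0L)
  c(total %/% 2L, total - total %/% 2L)
}

spatial_out <- function(n, k, stride, pad) {
  p <- pad_amounts(n, k, stride, pad)
  as.integer((n + p[1] + p[2] - k) %/% stride + 1L)
}

#' Infer per-layer output shapes of an architecture
#'
#' @param spec An `arch_spec`.
#' @return A named list: for spatial nodes a length-4 vector (three spatial
#'   sizes and channels); for flatten/gap/dense nodes a scalar feature
#'   length.
#' @export
infer_shapes <- function(spec) {
  shapes <- list(input = spec$input_shape)
  for (nd in spec$layers) {
    ins <- lapply(nd$input, function(i) {
      if (is.null(shapes[[i]])) stop("unknown input node: ", i)
      shapes[[i]]
    })
    shapes[[nd$id]] <- switch(
      nd$kind,
      conv = {
        s <- ins[[1]]
        c(vapply(s[1:3], spatial_out, integer(1), k = nd$k,
                 stride = nd$stride, pad = nd$pad), nd$filters)
      },
      pool = {
        s <- ins[[1]]
        c(vapply(s[1:3], spatial_out, integer(1), k = nd$k,
                 stride = nd$stride, pad = nd$pad), s[4])
      },
      flatten = as.integer(prod(ins[[1]])),
      gap = ins[[1]][4],
      dense = nd$units,
      concat = {
        sp <- vapply(ins, function(s) s[1:3], integer(3))
        if (any(sp != sp[, 1]))
          stop("concat: branch spatial shapes differ for node ", nd$id)
        c(ins[[1]][1:3], sum(vapply(ins, function(s) s[4], integer(1))))
      },
      stop("unknown node kind: ", nd$kind))
  }
  shapes
}

#' Count trainable parameters of an architecture
#'
#' Exact count of kernel weights and biases over all parameterised layers.
#'
#' @param spec An `arch_spec`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(spec) {
  shapes <- spec$shapes %||% infer_shapes(spec)
  total <- 0
  for (nd in spec$layers) {
    inshape <- shapes[[nd$input[1]]]
    total <- total + switch(
      nd$kind,
      conv = (nd$k^3 * inshape[4] + 1) * nd$filters,
      dense = (prod_features(inshape) + 1) * nd$units,
      0)
  }
  as.integer(total)
}

prod_features <- function(shape) if (length(shape) > 1L) prod(shape) else shape

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stacked 3D CNN architecture (final model family)
#'
#' Four valid-padding 3^3 convolutions (8, 16, 32, 64 filters, stride 1)
#' alternating with three 2^3/stride-2 max-pools, then flatten and a dense
#' stack of 32, 16 and 1 units. Spatial chain from a 40-voxel side:
#' 38, 19, 17, 8, 6, 3, 1.
#'
#' @param l2_lambda L2 penalty on kernel weights (default the full-batch
#'   training value 0.00098).
#' @return An `arch_spec`.
#' @export
build_stacked3d <- function(l2_lambda = 0.00098) {
  stopifnot(l2_lambda >= 0)
  layers <- list(
    node_conv("conv1", "input", 8),
    node_pool("pool1", "conv1"),
    node_conv("conv2", "pool1", 16),
    node_pool("pool2", "conv2"),
    node_conv("conv3", "pool2", 32),
    node_pool("pool3", "conv3"),
    node_conv("conv4", "pool3", 64),
    node_simple("flat", "flatten", "conv4"),
    node_dense("fc1", "flat", 32),
    node_dense("fc2", "fc1", 16),
    node_dense("out", "fc2", 1, activation = "linear"))
  new_arch_spec("stacked3d", layers, l2_lambda)
}

#' VGG-like 3D CNN architecture
#'
#' Stacked valid 3^3 convolutions with overlapping same-padded 3^3/stride-2
#' max-pools: conv(8) pool conv(16) conv(16) pool conv(32) conv(32)
#' conv(32) pool, flatten, one sigmoid output unit. Larger kernels are
#' factorised into stacks of 3^3 convolutions, which preserves the
#' receptive field while cutting parameters (see
#' [count_parameters_unfactorised]).
#'
#' @param l2_lambda L2 penalty on kernel weights (default 0.002).
#' @return An `arch_spec`.
#' @export
build_vgg_like <- function(l2_lambda = 0.002) {
  stopifnot(l2_lambda >= 0)
  op <- function(id, input) node_pool(id, input, k = 3L, stride = 2L,
                                      pad = "same")
  layers <- list(
    node_conv("conv1", "input", 8),
    op("pool1", "conv1"),
    node_conv("conv2a", "pool1", 16),
    node_conv("conv2b", "conv2a", 16),
    op("pool2", "conv2b"),
    node_conv("conv3a", "pool2", 32),
    node_conv("conv3b", "conv3a", 32),
    node_conv("conv3c", "conv3b", 32),
    op("pool3", "conv3c"),
    node_simple("flat", "flatten", "pool3"),
    node_dense("out", "flat", 1, activation = "linear"))
  new_arch_spec("vgg_like", layers, l2_lambda)
}

# Standard inception module: parallel 1^3 branch, 1^3 -> 3^3 branch
# (factorised 5^3), 1^3 -> 3^3 -> 3^3 branch (factorised 7^3 via two 3^3),
# and a pooled 1^3-projected branch, concatenated channel-wise.
inception_module <- function(prefix, input, widths) {
  w <- widths
  list(
    node_conv(paste0(prefix, "_b1"), input, w[1], k = 1L),
    node_conv(paste0(prefix, "_b2r"), input, w[2], k = 1L),
    node_conv(paste0(prefix, "_b2"), paste0(prefix, "_b2r"), w[2],
              pad = "same"),
    node_conv(paste0(prefix, "_b3r"), input, w[3], k = 1L),
    node_conv(paste0(prefix, "_b3a"), paste0(prefix, "_b3r"), w[3],
              pad = "same"),
    node_conv(paste0(prefix, "_b3"), paste0(prefix, "_b3a"), w[3],
              pad = "same"),
    node_pool(paste0(prefix, "_bp"), input, k = 3L, stride = 1L,
              pad = "same"),
    node_conv(paste0(prefix, "_b4"), paste0(prefix, "_bp"), w[4], k = 1L),
    node_simple(paste0(prefix, "_cat"), "concat",
                c(paste0(prefix, c("_b1", "_b2", "_b3", "_b4")))))
}

# Reduction module: stride-2 convolutional branches plus a stride-2
# max-pool pass-through, halving each spatial dimension (ceil).
reduction_module <- function(prefix, input, width) {
  list(
    node_conv(paste0(prefix, "_b1r"), input, width, k = 1L),
    node_conv(paste0(prefix, "_b1"), paste0(prefix, "_b1r"), width,
              stride = 2L, pad = "same"),
    node_conv(paste0(prefix, "_b2r"), input, width, k = 1L),
    node_conv(paste0(prefix, "_b2a"), paste0(prefix, "_b2r"), width,
              pad = "same"),
    node_conv(paste0(prefix, "_b2"), paste0(prefix, "_b2a"), width,
              stride = 2L, pad = "same"),
    node_pool(paste0(prefix, "_bp"), input, k = 3L, stride = 2L,
              pad = "same"),
    node_simple(paste0(prefix, "_cat"), "concat",
                paste0(prefix, c("_b1", "_b2", "_bp"))))
}

#' Inception-v2-like 3D CNN architecture
#'
#' A 3^3 stem convolution and max-pool, four standard inception modules
#' (parallel 1^3, factorised 3^3 stacks and a pooled branch, concatenated)
#' and two reduction modules, followed by global average pooling and one
#' sigmoid output unit. Branch widths default to (8, 8, 8, 8) before the
#' first reduction and (16, 16, 16, 16) after; both are configurable.
#'
#' @param l2_lambda L2 penalty on kernel weights (default 0.0006).
#' @param widths_early,widths_late Branch widths of the standard modules
#'   before/after the first reduction.
#' @param reduction_widths Convolutional branch widths of the two
#'   reduction modules.
#' @return An `arch_spec`.
#' @export
build_inception_like <- function(l2_lambda = 0.0006,
                                 widths_early = c(8, 8, 8, 8),
                                 widths_late = c(16, 16, 16, 16),
                                 reduction_widths = c(16, 32)) {
  stopifnot(l2_lambda >= 0)
  layers <- c(
    list(node_conv("stem", "input", 8),
         node_pool("stempool", "stem")),
    inception_module("inc1", "stempool", widths_early),
    inception_module("inc2", "inc1_cat", widths_early),
    reduction_module("red1", "inc2_cat", reduction_widths[1]),
    inception_module("inc3", "red1_cat", widths_late),
    inception_module("inc4", "inc3_cat", widths_late),
    reduction_module("red2", "inc4_cat", reduction_widths[2]),
    list(node_simple("gap", "gap", "red2_cat"),
         node_dense("out", "gap", 1, activation = "linear")))
  new_arch_spec("inception_like", layers, l2_lambda)
}

#' Parameter count of the unfactorised VGG-like variant
#'
#' Replaces each stacked pair/triple of 3^3 convolutions in the VGG-like
#' network by a single 5^3 or 7^3 convolution with the same receptive
#' field and output width, and counts its parameters. Factorisation of
#' convolutions reduces parameters far more strongly in 3D than in 2D, so
#' this count strictly exceeds `count_parameters(build_vgg_like())`.
#'
#' @return Integer parameter count of the unfactorised equivalent.
#' @export
count_parameters_unfactorised <- function() {
  # conv1 stays 3^3 x 8 on 1 channel; the (16,16) pair becomes one 5^3 x 16
  # on 8 channels; the (32,32,32) triple becomes one 7^3 x 32 on 16
  # channels; dense head identical (flatten width 32 -> 1).
  conv1 <- (3^3 * 1 + 1) * 8
  conv2 <- (5^3 * 8 + 1) * 16
  conv3 <- (7^3 * 16 + 1) * 32
  dense <- (32 + 1) * 1
  as.integer(conv1 + conv2 + conv3 + dense)
}
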