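# Forward/backward engine for the arch_spec DAG. Internal activation
# layout is (d, h, w, B, C) — spatial axes, batch, channels — so the
# im2col GEMM writes each convolution's output block without permutation
# copies; flatten/gap/dense nodes produce (B x features) matrices. The
# external input block convention is (d, h, w, 1, B) with a single
# channel, which is memory-identical to the internal layout.

#' He (variance-scaling) parameter initialisation
#'
#' Kernel weights are drawn from N(0, 2 / fan_in), the scheme designed for
#' rectified activations; biases start at zero.
#'
#' @param spec An `arch_spec`.
#' @param seed Optional integer seed.
#' @return A named list of `list(W, b)` per parameterised node.
#' @export
init_parameters <- function(spec, seed = NULL) {
  shapes <- spec$shapes
  with_seed(seed, {
    params <- list()
    for (nd in spec$layers) {
      if (nd$kind == "conv") {
        fan_in <- nd$k^3 * shapes[[nd$input[1]]][4]
        params[[nd$id]] <- list(
          W = matrix(rnorm(fan_in * nd$filters, 0, sqrt(2 / fan_in)),
                     fan_in, nd$filters),
          b = numeric(nd$filters))
      } else if (nd$kind == "dense") {
        fan_in <- prod_features(shapes[[nd$input[1]]])
        params[[nd$id]] <- list(
          W = matrix(rnorm(fan_in * nd$units, 0, sqrt(2 / fan_in)),
                     fan_in, nd$units),
          b = numeric(nd$units))
      }
    }
    params
  })
}

# Forward pass over a (d,h,w,1,B) input block. Returns logits plus, if
# keep_cache, everything backward_pass needs.
forward_pass <- function(spec, params, x, keep_cache = FALSE) {
  shapes <- spec$shapes
  xd <- dim(x)
  stopifnot(length(xd) == 5L, xd[4] == 1L)
  B <- xd[5]
  dim(x) <- c(xd[1:3], B, 1L)          # internal (d,h,w,B,C) layout
  acts <- list(input = x)
  cache <- list()
  alpha <- spec$leaky_alpha
  for (nd in spec$layers) {
    id <- nd$id
    a_in <- acts[[nd$input[1]]]
    if (nd$kind == "conv") {
      ind <- dim(a_in)
      p <- pad_amounts(ind[1], nd$k, nd$stride, nd$pad)
      cols <- im2col3(a_in, as.integer(ind), nd$k, nd$stride, p[1], p[2])
      out <- cols %*% params[[id]]$W
      bias_act_inplace(out, params[[id]]$b, alpha,
                       nd$activation == "leaky_relu")
      dim(out) <- c(shapes[[id]][1:3], B, nd$filters)
      acts[[id]] <- out
      if (keep_cache) cache[[id]] <- list(cols = cols, in_dims = ind,
                                          pad = p)
    } else if (nd$kind == "pool") {
      ind <- dim(a_in)
      p <- pad_amounts(ind[1], nd$k, nd$stride, nd$pad)
      mp <- maxpool3_fwd(a_in, as.integer(ind), nd$k, nd$stride,
                         p[1], p[2])
      out <- mp$out
      dim(out) <- mp$odims
      acts[[id]] <- out
      if (keep_cache) cache[[id]] <- list(which = mp$which, in_dims = ind)
    } else if (nd$kind == "flatten") {
      ind <- dim(a_in)
      nsp <- prod(ind[1:3])
      dim(a_in) <- c(nsp, ind[4], ind[5])
      a_in <- aperm(a_in, c(1, 3, 2))          # (nsp, C, B)
      acts[[id]] <- t(matrix(a_in, ncol = B))  # B x (spatial, channel)
    } else if (nd$kind == "gap") {
      ind <- dim(a_in)
      nsp <- prod(ind[1:3])
      acts[[id]] <- matrix(colMeans(matrix(a_in, nrow = nsp)),
                           nrow = B, ncol = ind[5])
      if (keep_cache) cache[[id]] <- list(in_dims = ind)
    } else if (nd$kind == "dense") {
      pre <- a_in %*% params[[id]]$W
      bias_act_inplace(pre, params[[id]]$b, alpha,
                       nd$activation == "leaky_relu")
      acts[[id]] <- pre
    } else if (nd$kind == "concat") {
      parts <- lapply(nd$input, function(i) acts[[i]])
      dsp <- dim(parts[[1]])[1:3]
      widths <- vapply(parts, function(p) dim(p)[5], integer(1))
      out <- unlist(lapply(parts, as.vector), use.names = FALSE)
      dim(out) <- c(dsp, B, sum(widths))
      acts[[id]] <- out
      if (keep_cache) cache[[id]] <- list(widths = widths)
    }
  }
  last <- spec$layers[[length(spec$layers)]]$id
  logits <- acts[[last]][, 1]
  if (keep_cache)
    list(logits = logits, acts = acts, cache = cache)
  else
    list(logits = logits)
}

# Backward pass from d(loss)/d(logit). Returns parameter gradients and,
# optionally, the gradient w.r.t. the output of the `capture` node
# (Grad-CAM). Gradients w.r.t. the input block itself are not formed.
backward_pass <- function(spec, params, fwd, dlogit, capture = NULL) {
  shapes <- spec$shapes
  acts <- fwd$acts
  cache <- fwd$cache
  alpha <- spec$leaky_alpha
  B <- length(dlogit)
  grads <- list()
  dacts <- list()
  last <- spec$layers[[length(spec$layers)]]$id
  dacts[[last]] <- matrix(dlogit, ncol = 1)
  captured <- NULL
  add_grad <- function(id, g) {
    if (identical(id, "input")) return(invisible(NULL))
    if (is.null(dacts[[id]])) dacts[[id]] <<- g
    else dacts[[id]] <<- dacts[[id]] + g
  }
  for (nd in rev(spec$layers)) {
    id <- nd$id
    dout <- dacts[[id]]
    if (is.null(dout)) next
    if (!is.null(capture) && identical(capture, id)) captured <- dout
    if (nd$kind == "dense") {
      if (nd$activation == "leaky_relu") {
        dout <- leaky_bwd(dout, acts[[id]], alpha)
        dim(dout) <- c(B, nd$units)
      }
      a_in <- acts[[nd$input[1]]]
      grads[[id]] <- list(W = crossprod(a_in, dout), b = colSums(dout))
      add_grad(nd$input[1], dout %*% t(params[[id]]$W))
    } else if (nd$kind == "flatten") {
      inshape <- dim(acts[[nd$input[1]]])
      nsp <- prod(inshape[1:3])
      g <- t(dout)                              # (spatial, channel) x B
      dim(g) <- c(nsp, inshape[5], B)
      g <- aperm(g, c(1, 3, 2))
      dim(g) <- inshape
      add_grad(nd$input[1], g)
    } else if (nd$kind == "gap") {
      ind <- cache[[id]]$in_dims
      nsp <- prod(ind[1:3])
      g <- rep(as.vector(dout) / nsp, each = nsp)
      dim(g) <- ind
      add_grad(nd$input[1], g)
    } else if (nd$kind == "conv") {
      if (nd$activation == "leaky_relu")
        dout <- leaky_bwd(dout, acts[[id]], alpha)
      nsp <- prod(shapes[[id]][1:3])
      dim(dout) <- c(nsp * B, nd$filters)
      cc <- cache[[id]]
      grads[[id]] <- list(W = crossprod(cc$cols, dout), b = colSums(dout))
      if (!identical(nd$input[1], "input") || !is.null(capture)) {
        dcols <- tcrossprod(dout, params[[id]]$W)
        dx <- col2im3(dcols, as.integer(cc$in_dims), nd$k, nd$stride,
                      cc$pad[1], cc$pad[2])
        dim(dx) <- cc$in_dims
        add_grad(nd$input[1], dx)
      }
    } else if (nd$kind == "pool") {
      cc <- cache[[id]]
      dx <- maxpool3_bwd(dout, cc$which, as.integer(cc$in_dims))
      dim(dx) <- cc$in_dims
      add_grad(nd$input[1], dx)
    } else if (nd$kind == "concat") {
      widths <- cache[[id]]$widths
      ind <- dim(acts[[id]])
      block <- prod(ind[1:4])
      v <- as.vector(dout)
      off <- 0
      for (j in seq_along(nd$input)) {
        g <- v[(off * block + 1):((off + widths[j]) * block)]
        dim(g) <- c(ind[1:4], widths[j])
        add_grad(nd$input[j], g)
        off <- off + widths[j]
      }
    }
    dacts[[id]] <- NULL  # free
  }
  list(grads = grads, captured = captured)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward inference: class probabilities for a batch of input tensors
#'
#' Deterministic given fixed parameters; large batches are processed in
#' memory-bounded chunks and results are identical to one-by-one
#' evaluation.
#'
#' @param model A `trained_model` (or any list with `spec` and `params`).
#' @param x A (40, 40, 40, 1, B) array, a list of 3D tensors, or a single
#'   3D tensor.
#' @param chunk Maximum samples per forward chunk.
#' @return Numeric vector of B malignancy probabilities in (0, 1).
#' @export
forward <- function(model, x, chunk = 16L) {
  x <- stack_tensors(x)
  exp_shape <- model$spec$input_shape
  if (!all(dim(x)[1:4] == exp_shape))
    stop("forward: input shape ", paste(dim(x)[1:4], collapse = "x"),
         " does not match the architecture input ",
         paste(exp_shape, collapse = "x"))
  B <- dim(x)[5]
  probs <- numeric(B)
  for (s in seq(1L, B, by = chunk)) {
    e <- min(s + chunk - 1L, B)
    xb <- x[, , , , s:e, drop = FALSE]
    probs[s:e] <- sigmoid(
      forward_pass(model$spec, model$params, xb)$logits)
  }
  probs
}

# Binary cross-entropy of probabilities against 0/1 labels.
bce_loss <- function(probs, y) {
  p <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# L2 penalty over kernel weights only (biases excluded).
l2_penalty <- function(params, lambda) {
  if (lambda <= 0) return(0)
  lambda * sum(vapply(params, function(p) sum(p$W^2), numeric(1)))
}
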