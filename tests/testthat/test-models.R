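test_that("stacked 3D CNN spatial chain and flatten width match the design", {
  spec <- build_stacked3d()
  sh <- spec$shapes
  chain <- vapply(c("conv1", "pool1", "conv2", "pool2", "conv3", "pool3",
                    "conv4"), function(id) sh[[id]][1], integer(1))
  expect_equal(unname(chain), c(38L, 19L, 17L, 8L, 6L, 3L, 1L))
  expect_equal(sh$flat, 64L)
  expect_equal(sh$conv4[4], 64L)
})

test_that("VGG-like spatial chain uses ceil division at same-padded pools", {
  spec <- build_vgg_like()
  sh <- spec$shapes
  chain <- vapply(c("conv1", "pool1", "conv2a", "conv2b", "pool2",
                    "conv3a", "conv3b", "conv3c", "pool3"),
                  function(id) sh[[id]][1], integer(1))
  expect_equal(unname(chain), c(38L, 19L, 17L, 15L, 8L, 6L, 4L, 2L, 1L))
  expect_equal(sh$flat, 32L)
})

test_that("inception modules concatenate branch widths and reductions halve", {
  spec <- build_inception_like()
  sh <- spec$shapes
  expect_equal(sh$inc1_cat[4], 8L + 8L + 8L + 8L)
  expect_equal(sh$inc1_cat[1], 19L)
  expect_equal(sh$red1_cat[1], 10L)    # ceil(19 / 2)
  expect_equal(sh$inc3_cat[4], 64L)
  expect_equal(sh$red2_cat[1], 5L)     # ceil(10 / 2)
  expect_equal(sh$gap, sh$red2_cat[4])
})

test_that("parameter counting matches closed forms", {
  nc <- petnodcnn:::node_conv; nd <- petnodcnn:::node_dense
  ns <- petnodcnn:::node_simple
  one_conv <- petnodcnn:::new_arch_spec(
    "t", list(nc("c", "input", 8),
              ns("f", "flatten", "c"),
              nd("out", "f", 1, activation = "linear")),
    0, input_shape = c(5L, 5L, 5L, 1L))
  # conv(8, 3^3) on one channel contributes 8 * (27 + 1) = 224
  expect_equal(count_parameters(one_conv), 224L + (27L * 8L + 1L))

  dense_only <- petnodcnn:::new_arch_spec(
    "t", list(ns("f", "flatten", "input"),
              nd("d", "f", 32), nd("out", "d", 1, activation = "linear")),
    0, input_shape = c(4L, 4L, 4L, 1L))
  # dense 64 -> 32 contributes 64 * 32 + 32 = 2080
  expect_equal(count_parameters(dense_only), 2080L + 33L)

  empty <- petnodcnn:::new_arch_spec("t", list(), 0,
                                     input_shape = c(4L, 4L, 4L, 1L))
  expect_equal(count_parameters(empty), 0L)
})

test_that("factorised convolutions cut parameters versus large kernels", {
  expect_lt(count_parameters(build_vgg_like()),
            count_parameters_unfactorised())
})

test_that("all three builders accept the 40^3 input and emit probabilities", {
  x <- array(runif(40^3), dim = c(40, 40, 40, 1, 1))
  for (build in list(build_stacked3d, build_vgg_like,
                     build_inception_like)) {
    spec <- build()
    model <- list(spec = spec, params = init_parameters(spec, seed = 2))
    p <- forward(model, x)
    expect_length(p, 1L)
    expect_gt(p, 0); expect_lt(p, 1)
  }
})

test_that("forward evaluation is deterministic and batching-equivalent", {
  spec <- tiny_spec()
  model <- list(spec = spec, params = init_parameters(spec, seed = 3))
  set.seed(10)
  x <- array(rnorm(8^3 * 5), dim = c(8, 8, 8, 1, 5))
  p1 <- forward(model, x)
  expect_identical(forward(model, x), p1)
  one_by_one <- vapply(1:5, function(i)
    forward(model, x[, , , , i, drop = FALSE]), numeric(1))
  expect_equal(one_by_one, p1, tolerance = 1e-6)
  expect_error(forward(model, array(0, dim = c(7, 8, 8, 1, 1))), "shape")
})

test_that("a zero output layer yields probability one half", {
  spec <- tiny_spec()
  params <- init_parameters(spec, seed = 1)
  params$out$W[] <- 0
  params$out$b[] <- 0
  x <- array(rnorm(8^3 * 3), dim = c(8, 8, 8, 1, 3))
  expect_equal(forward(list(spec = spec, params = params), x),
               rep(0.5, 3))
})

test_that("He initialisation hits the 2/fan_in variance for rectified layers", {
  spec <- build_stacked3d()
  params <- init_parameters(spec, seed = 4)
  for (id in c("conv3", "conv4")) {
    W <- params[[id]]$W
    fan_in <- nrow(W)
    expect_gt(length(W), 1e4)
    expect_lt(abs(var(as.vector(W)) - 2 / fan_in) / (2 / fan_in), 0.1)
    expect_true(all(params[[id]]$b == 0))
  }
})

test_that("LeakyReLU uses alpha = 0.3 exactly on the negative branch", {
  x <- c(-2, -0.5, 0, 0.5, 2)
  out <- petnodcnn:::leaky_fwd(x, 0.3)
  expect_equal(out, ifelse(x >= 0, x, 0.3 * x))
})

test_that("analytic gradients agree with finite differences on a branchy net", {
  spec <- tiny_branchy_spec()
  params <- init_parameters(spec, seed = 7)
  set.seed(42)
  x <- array(rnorm(8^3 * 2), dim = c(8, 8, 8, 1, 2))
  y <- c(1, 0)
  fp <- petnodcnn:::forward_pass
  bp <- petnodcnn:::backward_pass
  loss <- function(p) petnodcnn:::bce_loss(
    petnodcnn:::sigmoid(fp(spec, p, x)$logits), y)
  fwd <- fp(spec, params, x, keep_cache = TRUE)
  prob <- petnodcnn:::sigmoid(fwd$logits)
  bk <- bp(spec, params, fwd, (prob - y) / 2)
  eps <- 1e-6
  set.seed(1)
  for (id in names(bk$grads)) for (slot in c("W", "b")) {
    g <- bk$grads[[id]][[slot]]
    for (i in sample(length(g), min(4, length(g)))) {
      pp <- params; pp[[id]][[slot]][i] <- pp[[id]][[slot]][i] + eps
      pm <- params; pm[[id]][[slot]][i] <- pm[[id]][[slot]][i] - eps
      num <- (loss(pp) - loss(pm)) / (2 * eps)
      expect_lt(abs(num - g[i]) / max(1e-8, abs(num) + abs(g[i])), 1e-5)
    }
  }
})
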