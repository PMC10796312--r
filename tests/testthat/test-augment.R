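test_that("the default augmentation plan carries the class-specific factors", {
  plan <- augmentation_plan()
  expect_equal(plan$minority$n_translations, 20L)
  expect_equal(3L * plan$minority$n_rotations_per_axis, 21L)
  expect_equal(sum(plan$minority$noise_counts), 20L)
  expect_equal(plan$majority$n_translations, 16L)
  expect_equal(3L * plan$majority$n_rotations_per_axis, 15L)
  expect_equal(sum(plan$majority$noise_counts), 16L)
  expect_equal(plan$noise_sd, c(0.1, 0.3, 0.5))
  expect_equal(plan$translation_range_vox, 10L)
  expect_equal(plan$rotation_range_deg, 45)
})

test_that("translation displaces an impulse and zero-fills vacated voxels", {
  x <- array(0, dim = c(40, 40, 40))
  x[21, 21, 21] <- 1                 # 0-based (20, 20, 20)
  expect_identical(translate_tensor(x, c(0, 0, 0)), x)
  y <- translate_tensor(x, c(10, 0, 0))
  expect_equal(y[31, 21, 21], 1)     # 0-based (30, 20, 20)
  expect_equal(sum(y), 1)
  expect_error(translate_tensor(x, c(11, 0, 0)), "exceeds")

  # zero-fill: a full tensor shifted leaves exact zeros behind
  f <- array(1, dim = c(6, 6, 6))
  z <- translate_tensor(f, c(2, -1, 0), max_shift = 10)
  expect_true(all(z[1:2, , ] == 0))
  expect_true(all(z[, 6, ] == 0))
  expect_true(all(z[3:6, 1:5, ] == 1))
})

test_that("an impulse within 10 voxels of centre survives any legal shift", {
  # label-preservation property behind the 10-voxel (15 mm) shift bound
  set.seed(21)
  for (i in 1:25) {
    pos <- 20 + sample(-10:10, 3, replace = TRUE)   # 0-based nodule voxel
    shift <- sample(-10:10, 3, replace = TRUE)
    dst <- pos + shift
    expect_true(all(dst >= 0 & dst <= 39))
  }
})

test_that("rotation is a centre-axis composite with bilinear resampling", {
  set.seed(4)
  x <- array(runif(9^3), dim = c(9, 9, 9))
  expect_equal(rotate_tensor(x, "z", 0), x, tolerance = 1e-9)
  # the centre voxel is the fixed point of T^-1 R T
  for (ang in c(-45, -13.7, 30, 45)) {
    for (ax in c("x", "y", "z")) {
      r <- rotate_tensor(x, ax, ang)
      expect_equal(r[5, 5, 5], x[5, 5, 5], tolerance = 1e-9)
    }
  }
  expect_error(rotate_tensor(x, "z", 46), "exceeds")

  # a rotationally symmetric blob is invariant up to interpolation error
  g <- seq_len(21) - 11
  blob <- exp(-outer(outer(g^2, g^2, "+"), g^2, "+") / (2 * 3^2))
  r45 <- rotate_tensor(blob, "z", 45)
  expect_lt(max(abs(r45 - blob)), 0.03)
  expect_gt(max(blob), 0.99)         # sanity: non-trivial field

  # bilinear resampling is exact on an in-plane linear field, so the
  # rotated tensor must match the analytic composite transform
  d <- c(11, 11, 5)
  ctr <- (d[1:2] - 1) / 2
  u <- rep(seq_len(d[1]) - 1 - ctr[1], times = d[2])
  v <- rep(seq_len(d[2]) - 1 - ctr[2], each = d[1])
  plane <- array(rep(0.3 * u + 0.7 * v, times = d[3]), dim = d)
  theta <- 25 * pi / 180
  su <- cos(theta) * u + sin(theta) * v
  sv <- -sin(theta) * u + cos(theta) * v
  inside <- abs(su) <= ctr[1] & abs(sv) <= ctr[2]
  expected <- ifelse(inside, 0.3 * su + 0.7 * sv, 0)
  got <- rotate_tensor(plane, "z", 25)
  for (k in seq_len(d[3]))
    expect_equal(as.vector(got[, , k])[inside],
                 expected[inside], tolerance = 1e-9)
})

test_that("noise injection is calibrated, seeded, and additive", {
  x <- array(0, dim = c(40, 40, 40))
  y <- add_noise(x, 0.3, seed = 5)
  expect_gte(sd(y), 0.29)            # chi-square bound at n = 64000
  expect_lte(sd(y), 0.31)
  expect_identical(add_noise(x, 0.3, seed = 5), y)
  expect_equal(add_noise(x, 1e-12, seed = 1), x, tolerance = 1e-9)
})

test_that("per-subject augmentation yields the class-specific complement", {
  plan <- augmentation_plan(seed = 7)
  x <- array(runif(12^3), dim = c(12, 12, 12))
  minority <- augment_subject(x, "minority", plan, seed = 1)
  expect_length(minority, 61L)       # 20 + 21 + 20
  majority <- augment_subject(x, "majority", plan, seed = 1)
  expect_length(majority, 47L)       # 16 + 15 + 16
  types <- vapply(minority, function(t) attr(t, "transform")$type,
                  character(1))
  expect_equal(as.integer(table(types)[c("translation", "rotation",
                                         "noise")]),
               c(20L, 21L, 20L))
  # rotations evenly apportioned per axis
  axes <- vapply(minority[types == "rotation"],
                 function(t) attr(t, "transform")$axis, character(1))
  expect_equal(as.integer(table(axes)), c(7L, 7L, 7L))

  empty <- augmentation_plan(
    minority = list(n_translations = 0L, n_rotations_per_axis = 0L,
                    noise_counts = c(0L, 0L, 0L)),
    majority = list(n_translations = 0L, n_rotations_per_axis = 0L,
                    noise_counts = c(0L, 0L, 0L)))
  expect_length(augment_subject(x, "minority", empty, seed = 1), 0L)
})

test_that("dataset-level counts follow the closed form for random plans", {
  set.seed(13)
  for (rep in 1:4) {
    plan <- augmentation_plan(
      minority = list(n_translations = sample(0:4, 1),
                      n_rotations_per_axis = sample(0:2, 1),
                      noise_counts = sample(0:2, 3, replace = TRUE)),
      majority = list(n_translations = sample(0:4, 1),
                      n_rotations_per_axis = sample(0:2, 1),
                      noise_counts = sample(0:2, 3, replace = TRUE)),
      seed = rep)
    n_min <- sample(1:3, 1); n_maj <- sample(1:4, 1)
    labels <- rep(c("malignant", "benign"), c(n_min, n_maj))
    tensors <- lapply(seq_along(labels), function(i)
      array(runif(6^3), dim = c(6, 6, 6)))
    ds <- build_augmented_dataset(tensors, labels, plan)
    expect_length(ds$tensors, augmented_dataset_size(plan, n_min, n_maj))
    expect_equal(sum(!ds$is_augmented), length(labels))
    # labels preserved under augmentation
    expect_equal(as.character(ds$labels),
                 rep(labels, times = table(ds$subject_id)[
                   unique(ds$subject_id)]))
  }
})

test_that("the study plan approximately balances a 41/49 cohort", {
  plan <- augmentation_plan()
  total <- augmented_dataset_size(plan, 41, 49)
  minority_images <- 41 * (1 + 61)
  frac <- minority_images / total
  expect_gte(frac, 0.48)
  expect_lte(frac, 0.55)
})

test_that("a single minority original expands to 62 images", {
  plan <- augmentation_plan(seed = 3)
  ds <- build_augmented_dataset(
    list(S1 = array(runif(8^3), dim = c(8, 8, 8))), "malignant", plan)
  expect_length(ds$tensors, 62L)
  ds0 <- build_augmented_dataset(list(), factor(character(0),
                                               c("benign", "malignant")),
                                 plan)
  expect_length(ds0$tensors, 0L)
})

test_that("augmentation is reproducible subject-by-subject", {
  plan <- augmentation_plan(seed = 11)
  x <- array(runif(8^3), dim = c(8, 8, 8))
  a <- augment_subject(x, "majority", plan, seed = sub_seed(plan$seed, "S1"))
  b <- augment_subject(x, "majority", plan, seed = sub_seed(plan$seed, "S1"))
  expect_identical(a, b)
})
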