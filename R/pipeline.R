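#' End-to-end experiment configuration
#'
#' Aggregates every stage's settings: phantom cohort, preprocessing,
#' optional augmentation, architecture, training, and evaluation. The
#' single `seed` drives every random draw through documented sub-seeding.
#' Round-trips losslessly through YAML ([write_experiment_config] /
#' [read_experiment_config]).
#'
#' @param phantom A [phantom_spec].
#' @param arch `"stacked3d"`, `"vgg_like"` or `"inception_like"`.
#' @param l2_lambda L2 penalty; `NULL` takes the architecture default.
#' @param train A [train_config].
#' @param augment Logical: apply offline augmentation to fold training
#'   sets.
#' @param augment_plan An [augmentation_plan] (used when `augment` is
#'   TRUE).
#' @param crop_side_mm Side of the nodule-centred crop cube (mm).
#' @param target_voxel_mm Isotropic resampling target (mm).
#' @param min_sens Minimum sensitivity of the constrained threshold rule.
#' @param ci_level Confidence level of the test-set AUC interval.
#' @param n_permutations Permutations of the Venkatraman-Begg test.
#' @param gradcam_gallery Logical: write Grad-CAM fusion galleries for the
#'   test subjects.
#' @param seed Global experiment seed.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              arch = c("stacked3d", "vgg_like",
                                       "inception_like"),
                              l2_lambda = NULL,
                              train = train_config(),
                              augment = FALSE,
                              augment_plan = augmentation_plan(),
                              crop_side_mm = 60,
                              target_voxel_mm = 1.5,
                              min_sens = 0.95,
                              ci_level = 0.95,
                              n_permutations = 2000L,
                              gradcam_gallery = FALSE,
                              seed = 1L) {
  arch <- match.arg(arch)
  structure(list(phantom = phantom, arch = arch, l2_lambda = l2_lambda,
                 train = train, augment = augment,
                 augment_plan = augment_plan,
                 crop_side_mm = crop_side_mm,
                 target_voxel_mm = target_voxel_mm, min_sens = min_sens,
                 ci_level = ci_level,
                 n_permutations = as.integer(n_permutations),
                 gradcam_gallery = gradcam_gallery,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

build_architecture <- function(config) {
  builder <- switch(config$arch, stacked3d = build_stacked3d,
                    vgg_like = build_vgg_like,
                    inception_like = build_inception_like)
  if (is.null(config$l2_lambda)) builder() else builder(config$l2_lambda)
}

#' Write / read an experiment configuration as YAML
#'
#' @param config An [experiment_config].
#' @param path YAML file path.
#' @return `path` invisibly (write); an [experiment_config] (read).
#' @export
write_experiment_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  experiment_config(
    phantom = do.call(phantom_spec, raw$phantom),
    arch = raw$arch, l2_lambda = raw$l2_lambda,
    train = do.call(train_config, raw$train),
    augment = raw$augment,
    augment_plan = do.call(augmentation_plan, raw$augment_plan),
    crop_side_mm = raw$crop_side_mm,
    target_voxel_mm = raw$target_voxel_mm, min_sens = raw$min_sens,
    ci_level = raw$ci_level, n_permutations = raw$n_permutations,
    gradcam_gallery = raw$gradcam_gallery, seed = raw$seed)
}

# Load a cohort from disk and preprocess every subject: isotropic
# resampling, nodule-centred crop, SUVmax scoring.
preprocess_cohort <- function(manifest, config) {
  tensors <- list()
  suvmax <- numeric(nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    vol <- read_nrrd(manifest$path[i])
    vol$subject_id <- manifest$subject_id[i]
    iso <- resample_isotropic(vol, config$target_voxel_mm)
    centre <- c(manifest$center_x_mm[i], manifest$center_y_mm[i],
                manifest$center_z_mm[i])
    tensors[[manifest$subject_id[i]]] <-
      crop_cube(iso, centre, config$crop_side_mm)
    ann <- nodule_annotation(centre, manifest$diameter_mm[i],
                             manifest$label[i])
    suvmax[i] <- suvmax_score(iso, ann)
  }
  list(tensors = tensors, suvmax = suvmax)
}

#' Run the full experiment
#'
#' Executes simulate, preprocess, split, (augment), cross-validate,
#' ensemble, test-set evaluation (AUC with confidence interval, both
#' threshold rules with confusion metrics), the SUVmax comparison with
#' crossing-dispatched paired test, and optionally the Grad-CAM gallery.
#' The held-out test partition is touched exactly once, at the end. All
#' artifacts plus a machine-readable `summary.json` are written to
#' `out_dir`.
#'
#' @param config An [experiment_config].
#' @param out_dir Run directory (created if missing).
#' @return The summary list, invisibly; also serialised to
#'   `summary.json`.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(inherits(config, "experiment_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }

  phantom <- config$phantom
  phantom$seed <- sub_seed(config$seed, "cohort")
  manifest <- stage("simulate",
                    generate_cohort(phantom, file.path(out_dir, "cohort")))
  prep <- stage("preprocess", preprocess_cohort(manifest, config))
  labels <- manifest$label
  names(labels) <- manifest$subject_id

  split <- stage("split",
                 stratified_split(manifest,
                                  seed = sub_seed(config$seed, "split")))
  split_df <- data.frame(subject_id = names(split$assignment),
                         partition = as.character(split$assignment))
  jsonlite::write_json(split_df, file.path(out_dir, "split.json"))

  arch <- build_architecture(config)
  tconfig <- config$train
  tconfig$seed <- sub_seed(config$seed, "train")
  plan <- NULL
  if (isTRUE(config$augment)) {
    plan <- config$augment_plan
    plan$seed <- sub_seed(config$seed, "augment")
  }
  cv <- stage("cross_validate",
              cross_validate(arch, prep$tensors, labels, split, tconfig,
                             augment_plan = plan))
  ensemble <- build_ensemble(cv)

  # fold-specific thresholds chosen on each fold's validation partition
  ids <- names(split$assignment)
  fold_thresholds <- stage("thresholds", {
    lapply(1:4, function(k) {
      va_ids <- ids[split_indices(split, split$cv_partitions[k])]
      x <- lapply(prep$tensors[va_ids], apply_minmax,
                  stats = cv$fold_stats[[k]])
      p <- forward(cv$fold_models[[k]], x)
      yv <- labels[va_ids]
      list(youden = youden_threshold(p, yv),
           constrained = constrained_threshold(p, yv,
                                               min_sens = config$min_sens))
    })
  })
  thr_youden <- average_thresholds(lapply(fold_thresholds, `[[`, "youden"))
  thr_constr <- average_thresholds(lapply(fold_thresholds, `[[`,
                                          "constrained"))

  # held-out test partition: touched exactly once, from here on
  test_ids <- ids[split_indices(split, split$test_partition)]
  y_test <- labels[test_ids]
  eval_res <- stage("evaluate", {
    p_test <- predict(ensemble, prep$tensors[test_ids])
    ci <- delong_ci(p_test, y_test, level = config$ci_level)
    list(p_test = p_test, ci = ci)
  })
  p_test <- eval_res$p_test

  conf_youden <- confusion_metrics(classify_malignant(p_test, thr_youden),
                                   y_test)
  conf_constr <- confusion_metrics(classify_malignant(p_test, thr_constr),
                                   y_test)

  comparison <- stage("compare_suvmax", {
    suv_test <- prep$suvmax[match(test_ids, manifest$subject_id)]
    roc_cnn <- empirical_roc(p_test, y_test)
    roc_suv <- empirical_roc(suv_test, y_test)
    crossing <- curves_cross(roc_cnn, roc_suv)
    if (crossing) {
      vb <- venkatraman_begg_test(p_test, suv_test, y_test,
                                  n_permutations = config$n_permutations,
                                  seed = sub_seed(config$seed, "vb"))
      list(method = "venkatraman_begg", crossing = TRUE,
           statistic = vb$e_stat, p_value = vb$p_value,
           auc_cnn = roc_cnn$auc, auc_suvmax = roc_suv$auc,
           roc_cnn = roc_cnn, roc_suv = roc_suv)
    } else {
      dl <- delong_paired_test(p_test, suv_test, y_test)
      list(method = "delong", crossing = FALSE, statistic = dl$z,
           p_value = dl$p_value, auc_cnn = roc_cnn$auc,
           auc_suvmax = roc_suv$auc, roc_cnn = roc_cnn, roc_suv = roc_suv)
    }
  })
  roc_df <- rbind(
    data.frame(model = "cnn", fpr = comparison$roc_cnn$fpr,
               tpr = comparison$roc_cnn$tpr),
    data.frame(model = "suvmax", fpr = comparison$roc_suv$fpr,
               tpr = comparison$roc_suv$tpr))
  write.csv(roc_df, file.path(out_dir, "roc_test.csv"), row.names = FALSE)

  if (isTRUE(config$gradcam_gallery)) {
    stage("explain", {
      dir.create(file.path(out_dir, "gradcam"), showWarnings = FALSE)
      for (id in test_ids)
        gradcam_gallery(ensemble, prep$tensors[[id]],
                        file.path(out_dir, "gradcam",
                                  paste0(id, ".png")))
    })
  }

  summary <- list(
    schema_version = "1.0",
    seed = config$seed,
    arch = config$arch,
    augment = isTRUE(config$augment),
    n_subjects = nrow(manifest),
    n_malignant = sum(manifest$label == "malignant"),
    n_test = length(test_ids),
    fold_auc = cv$fold_auc,
    cv_mean_auc = cv$mean_auc,
    cv_sd_auc = cv$sd_auc,
    ensemble_weights = ensemble$weights,
    test_auc = eval_res$ci$auc,
    test_auc_ci = c(eval_res$ci$ci_low, eval_res$ci$ci_high),
    threshold_youden = thr_youden,
    threshold_constrained = thr_constr,
    confusion_youden = conf_youden,
    confusion_constrained = conf_constr,
    suvmax_auc = comparison$auc_suvmax,
    comparison_method = comparison$method,
    comparison_statistic = comparison$statistic,
    comparison_p = comparison$p_value,
    sub_seeds = list(cohort = phantom$seed,
                     split = sub_seed(config$seed, "split"),
                     train = sub_seed(config$seed, "train"),
                     vb = sub_seed(config$seed, "vb")))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  metrics <- data.frame(fold = 1:4, auc = cv$fold_auc,
                        train_size = cv$train_sizes)
  write.csv(metrics, file.path(out_dir, "metrics.csv"), row.names = FALSE)
  invisible(summary)
}
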