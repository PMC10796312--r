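#' Stratified five-way split of a cohort
#'
#' Randomly assigns subjects to five partitions P1..P5, stratified by the
#' target class with largest-remainder allocation: each class contributes
#' `floor(n_class / 5)` subjects per partition and its remainder subjects
#' are dealt to the partitions with the smallest running totals (ties to
#' the lower partition index), so per-partition class counts stay within
#' one of proportional and partition totals are balanced. P1..P4 feed the
#' 4-fold cross-validation; P5 is the held-out test partition.
#'
#' @param labels Benign/malignant labels, or a `cohort_manifest` (whose
#'   `label` column and `subject_id`s are used).
#' @param seed Integer seed.
#' @return An object of class `fold_split`: `assignment` (factor P1..P5
#'   named by subject id), `test_partition`, `cv_partitions`, `seed`.
#' @export
stratified_split <- function(labels, seed = 1L) {
  if (inherits(labels, "cohort_manifest") || is.data.frame(labels)) {
    ids <- labels$subject_id
    labels <- labels$label
  } else {
    ids <- names(labels) %||% sprintf("S%03d", seq_along(labels))
  }
  labels <- as_nodule_label(labels)
  n_part <- 5L
  counts <- table(labels)
  if (any(counts < n_part))
    stop("stratified_split: every class needs at least ", n_part,
         " subjects")
  quota <- matrix(0L, nrow = n_part, ncol = length(counts),
                  dimnames = list(NULL, names(counts)))
  for (cls in names(counts)) {
    base <- counts[[cls]] %/% n_part
    rem <- counts[[cls]] %% n_part
    quota[, cls] <- base
    if (rem > 0L) {
      # deal remainders to the partitions with smallest planned totals
      ord <- order(rowSums(quota), seq_len(n_part))
      quota[ord[seq_len(rem)], cls] <- base + 1L
    }
  }
  assignment <- with_seed(seed, {
    out <- character(length(labels))
    for (cls in names(counts)) {
      members <- sample(which(labels == cls))
      parts <- rep(paste0("P", seq_len(n_part)), times = quota[, cls])
      out[members] <- parts
    }
    out
  })
  assignment <- factor(assignment, levels = paste0("P", seq_len(n_part)))
  names(assignment) <- ids
  structure(list(assignment = assignment, test_partition = "P5",
                 cv_partitions = paste0("P", 1:4), seed = as.integer(seed)),
            class = "fold_split")
}

split_indices <- function(split, partition) {
  which(split$assignment %in% partition)
}

#' 4-fold cross-validation of an architecture
#'
#' For each fold k, partition Pk is the validation set and the remaining
#' three cross-validation partitions form the training set. Min-max
#' normalisation statistics are fitted on the fold's original training
#' tensors and applied to both sets; when an augmentation plan is given
#' the (normalised) training tensors are augmented offline while
#' evaluation always uses the original, never-augmented validation
#' partition. The held-out test partition is never touched.
#'
#' @param spec An `arch_spec`.
#' @param tensors List (or 5D array) of raw cropped input tensors for the
#'   whole cohort, named/ordered as the split assignment.
#' @param labels Benign/malignant labels aligned with `tensors`.
#' @param split A `fold_split`.
#' @param config A [train_config]; fold seeds are sub-seeded from it.
#' @param augment_plan Optional [augmentation_plan].
#' @return An object of class `cv_result`: per-fold models, normalisation
#'   stats, validation AUCs, their mean and sd, and fold training sizes.
#' @export
cross_validate <- function(spec, tensors, labels, split, config,
                           augment_plan = NULL) {
  stopifnot(inherits(split, "fold_split"))
  if (is.array(tensors))
    tensors <- lapply(seq_len(dim(tensors)[5]),
                      function(i) tensors[, , , 1L, i])
  labels <- as_nodule_label(labels)
  ids <- names(split$assignment)
  if (!is.null(names(tensors)))
    stopifnot(identical(sort(names(tensors)), sort(ids)))
  else
    names(tensors) <- ids
  fold_models <- list()
  fold_stats <- list()
  fold_auc <- numeric(4)
  train_sizes <- integer(4)
  for (k in 1:4) {
    val_part <- split$cv_partitions[k]
    train_parts <- setdiff(split$cv_partitions, val_part)
    tr_ids <- ids[split_indices(split, train_parts)]
    va_ids <- ids[split_indices(split, val_part)]
    stats <- fit_minmax(tensors[tr_ids], fold_id = paste0("F", k))
    x_tr <- lapply(tensors[tr_ids], apply_minmax, stats = stats)
    y_tr <- labels[match(tr_ids, ids)]
    if (!is.null(augment_plan)) {
      aug <- build_augmented_dataset(x_tr, y_tr, augment_plan)
      x_tr <- aug$tensors
      y_tr <- aug$labels
    }
    x_va <- lapply(tensors[va_ids], apply_minmax, stats = stats)
    y_va <- labels[match(va_ids, ids)]
    fold_config <- config
    fold_config$seed <- sub_seed(config$seed, paste0("fold", k))
    model <- train_model(spec, x_tr, y_tr, x_va, y_va, fold_config)
    probs <- forward(model, x_va)
    fold_auc[k] <- empirical_roc(probs, y_va)$auc
    fold_models[[k]] <- model
    fold_stats[[k]] <- stats
    train_sizes[k] <- length(tr_ids)
  }
  structure(list(fold_models = fold_models, fold_stats = fold_stats,
                 fold_auc = fold_auc, mean_auc = mean(fold_auc),
                 sd_auc = sd(fold_auc), train_sizes = train_sizes,
                 split = split),
            class = "cv_result")
}

#' Repeated cross-validation
#'
#' Retrains and re-evaluates the cross-validation under identical
#' conditions for several iterations with varied seeds, and reports the
#' across-iteration mean of the fold-mean AUC (the selection statistic
#' used to compare architectures).
#'
#' @inheritParams cross_validate
#' @param iterations Number of repetitions (>= 1).
#' @return A list with `iteration_mean_auc` (per-iteration fold means),
#'   `mean_auc` (their average), and `runs` (the `cv_result` objects).
#' @export
repeat_cv <- function(spec, tensors, labels, split, config,
                      augment_plan = NULL, iterations = 10L) {
  stopifnot(iterations >= 1L)
  runs <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    it_config <- config
    if (it > 1L)   # iteration 1 reproduces a plain cross_validate call
      it_config$seed <- sub_seed(config$seed, paste0("iteration", it))
    runs[[it]] <- cross_validate(spec, tensors, labels, split, it_config,
                                 augment_plan)
  }
  means <- vapply(runs, function(r) r$mean_auc, numeric(1))
  list(iteration_mean_auc = means, mean_auc = mean(means), runs = runs)
}

#' Build the size-weighted ensemble of the four fold models
#'
#' The ensemble probability is the average of the four fold models'
#' probabilities weighted by the size of each fold's training partition;
#' each fold model normalises inputs with its own fold statistics.
#'
#' @param cv A `cv_result` from [cross_validate] (exactly 4 fold models).
#' @return An object of class `ensemble_model` with `fold_models`,
#'   `fold_stats`, and `weights` summing to one.
#' @export
build_ensemble <- function(cv) {
  stopifnot(inherits(cv, "cv_result"), length(cv$fold_models) == 4L)
  w <- cv$train_sizes / sum(cv$train_sizes)
  if (abs(sum(w) - 1) > 1e-12 || any(w <= 0))
    stop("build_ensemble: weight normalisation failure")
  structure(list(fold_models = cv$fold_models, fold_stats = cv$fold_stats,
                 weights = w),
            class = "ensemble_model")
}

#' Ensemble prediction
#'
#' @param object An `ensemble_model`.
#' @param tensors Raw (un-normalised) input tensors: list of 3D arrays or
#'   a 5D block.
#' @param ... Unused.
#' @return Weighted-average malignancy probabilities.
#' @export
predict.ensemble_model <- function(object, tensors, ...) {
  if (is.array(tensors) && length(dim(tensors)) == 3L)
    tensors <- list(tensors)
  if (is.array(tensors))
    tensors <- lapply(seq_len(dim(tensors)[5]),
                      function(i) tensors[, , , 1L, i])
  probs <- 0
  for (k in seq_along(object$fold_models)) {
    x <- lapply(tensors, apply_minmax, stats = object$fold_stats[[k]])
    probs <- probs + object$weights[k] * forward(object$fold_models[[k]], x)
  }
  probs
}
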