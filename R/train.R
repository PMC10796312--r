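#' Training configuration
#'
#' Houses the optimiser and regularisation settings of a training run:
#' Adam on binary cross-entropy plus an L2 kernel penalty, epoch-wise
#' shuffling, and early stopping on the validation loss with a patience of
#' ten or a maximum of 100 epochs. `batch_size = "full"` means full-batch
#' learning on whatever the actual training-set size is.
#'
#' @param learning_rate Adam step size.
#' @param batch_size Positive integer or `"full"`.
#' @param l2_lambda L2 penalty on kernel weights; `NULL` takes the value
#'   carried by the architecture spec.
#' @param max_epochs Maximum number of epochs.
#' @param patience Early-stopping patience (epochs without validation-loss
#'   improvement); must be below `max_epochs`.
#' @param beta1,beta2,epsilon Adam moment decay rates and stabiliser.
#' @param seed Integer seed for initialisation and shuffling.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = "full",
                         l2_lambda = NULL, max_epochs = 100L,
                         patience = 10L, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-7, seed = 1L) {
  stopifnot(learning_rate > 0, max_epochs >= 1L, patience >= 1L,
            patience < max_epochs)
  if (!identical(batch_size, "full"))
    stopifnot(is.numeric(batch_size), batch_size >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 l2_lambda = l2_lambda, max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), beta1 = beta1,
                 beta2 = beta2, epsilon = epsilon, seed = as.integer(seed)),
            class = "train_config")
}

# One Adam step over the parameter list; state carries first/second moments.
adam_step <- function(params, grads, state, config, lambda) {
  state$t <- state$t + 1L
  lr_t <- config$learning_rate *
    sqrt(1 - config$beta2^state$t) / (1 - config$beta1^state$t)
  for (id in names(grads)) {
    for (slot in c("W", "b")) {
      g <- grads[[id]][[slot]]
      if (slot == "W" && lambda > 0) g <- g + 2 * lambda * params[[id]][[slot]]
      if (is.null(state$m[[id]][[slot]])) {
        state$m[[id]][[slot]] <- g * 0
        state$v[[id]][[slot]] <- g * 0
      }
      state$m[[id]][[slot]] <- config$beta1 * state$m[[id]][[slot]] +
        (1 - config$beta1) * g
      state$v[[id]][[slot]] <- config$beta2 * state$v[[id]][[slot]] +
        (1 - config$beta2) * g^2
      params[[id]][[slot]] <- params[[id]][[slot]] -
        lr_t * state$m[[id]][[slot]] /
        (sqrt(state$v[[id]][[slot]]) + config$epsilon)
    }
  }
  list(params = params, state = state)
}

#' Train a 3D CNN with Adam and early stopping
#'
#' Optimises binary cross-entropy plus the L2 kernel penalty with Adam.
#' The training set is reshuffled every epoch; gradients of batches larger
#' than `chunk` samples are accumulated over memory-bounded micro-chunks
#' (numerically identical to a single large batch). Training stops when
#' the validation loss has not improved for `patience` epochs or at
#' `max_epochs`; the returned parameters are those of the best-validation
#' epoch. Training on a single CPU with a fixed seed is fully
#' deterministic.
#'
#' @param spec An `arch_spec`.
#' @param x_train,y_train Training tensors ((d,h,w,1,B) array or list) and
#'   benign/malignant labels.
#' @param x_val,y_val Validation tensors and labels (never augmented).
#' @param config A [train_config].
#' @param chunk Micro-chunk size for gradient accumulation.
#' @return An object of class `trained_model`: `spec`, `params`, `history`
#'   (per-epoch train/val loss), `best_epoch`, `config`.
#' @export
train_model <- function(spec, x_train, y_train, x_val, y_val, config,
                        chunk = 16L) {
  stopifnot(inherits(spec, "arch_spec"), inherits(config, "train_config"))
  x_train <- stack_tensors(x_train)
  x_val <- stack_tensors(x_val)
  y_train <- as_binary_labels(y_train)
  y_val <- as_binary_labels(y_val)
  n <- dim(x_train)[5]
  if (n == 0L || dim(x_val)[5] == 0L)
    stop("train_model: empty training or validation set")
  stopifnot(length(y_train) == n, length(y_val) == dim(x_val)[5])
  lambda <- config$l2_lambda %||% spec$l2_lambda
  bs <- if (identical(config$batch_size, "full")) n else
    min(as.integer(config$batch_size), n)

  params <- init_parameters(spec, seed = sub_seed(config$seed, "init"))
  state <- list(t = 0L, m = list(), v = list())
  best <- list(val = Inf, params = params, epoch = 0L)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  strikes <- 0L

  with_seed(sub_seed(config$seed, "shuffle"), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (bstart in seq(1L, n, by = bs)) {
        bidx <- ord[bstart:min(bstart + bs - 1L, n)]
        nb <- length(bidx)
        # accumulate gradients over micro-chunks of the batch
        gacc <- NULL
        batch_probs <- numeric(nb)
        for (cstart in seq(1L, nb, by = chunk)) {
          cidx <- bidx[cstart:min(cstart + chunk - 1L, nb)]
          xb <- x_train[, , , , cidx, drop = FALSE]
          yb <- y_train[cidx]
          fwd <- forward_pass(spec, params, xb, keep_cache = TRUE)
          p <- sigmoid(fwd$logits)
          batch_probs[cstart:(cstart + length(cidx) - 1L)] <- p
          dlogit <- (p - yb) / nb
          bk <- backward_pass(spec, params, fwd, dlogit)
          if (is.null(gacc)) gacc <- bk$grads
          else for (id in names(gacc)) {
            gacc[[id]]$W <- gacc[[id]]$W + bk$grads[[id]]$W
            gacc[[id]]$b <- gacc[[id]]$b + bk$grads[[id]]$b
          }
        }
        ep_loss <- ep_loss + nb * bce_loss(batch_probs, y_train[bidx])
        upd <- adam_step(params, gacc, state, config, lambda)
        params <- upd$params
        state <- upd$state
      }
      train_loss <- ep_loss / n + l2_penalty(params, lambda)
      val_loss <- bce_loss(
        forward(list(spec = spec, params = params), x_val, chunk = chunk),
        y_val)
      history <- rbind(history,
                       data.frame(epoch = epoch, train_loss = train_loss,
                                  val_loss = val_loss))
      if (val_loss < best$val) {
        best <- list(val = val_loss, params = params, epoch = epoch)
        strikes <- 0L
      } else {
        strikes <- strikes + 1L
        if (strikes >= config$patience) break
      }
    }
  })
  structure(list(spec = spec, params = best$params, history = history,
                 best_epoch = best$epoch, config = config),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf(
    "<trained_model %s: %d epochs run, best epoch %d (val loss %.4f), %d parameters>\n",
    x$spec$family, nrow(x$history), x$best_epoch,
    min(x$history$val_loss), count_parameters(x$spec)))
  invisible(x)
}
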