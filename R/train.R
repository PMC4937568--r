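#' Training configuration
#'
#' Minibatch stochastic gradient descent with RMSprop per-parameter
#' updates and validation-based early stopping. Defaults: batch 128,
#' learning rate 0.002, RMSprop decay 0.98, epsilon 1e-8, patience 12
#' epochs, at most 100 epochs.
#'
#' @param batch_size sequences per minibatch.
#' @param learning_rate RMSprop step size.
#' @param rmsprop_decay decay of the squared-gradient accumulator, in (0,1).
#' @param epsilon accumulator floor to keep updates finite.
#' @param patience stop after this many consecutive epochs without a
#'   strictly lower validation loss.
#' @param max_epochs hard cap on epochs.
#' @param weight_decay L2 penalty coefficient applied to weight matrices
#'   (not to biases or batch-norm scale/shift). Zero by default; a small
#'   value (around 1e-3) is useful in small-data regimes, where it also
#'   shrinks the filter-weight components that receive no gradient
#'   signal and thereby keeps first-layer filters interpretable.
#' @param seed integer seed driving minibatch shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return a `train_config` list.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 0.002,
                         rmsprop_decay = 0.98, epsilon = 1e-8,
                         patience = 12L, max_epochs = 100L,
                         weight_decay = 0, seed = 1L,
                         verbose = FALSE) {
  stopifnot(batch_size >= 1, learning_rate > 0,
            rmsprop_decay > 0, rmsprop_decay < 1, weight_decay >= 0,
            patience >= 1, max_epochs >= 1, patience <= max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 rmsprop_decay = rmsprop_decay, epsilon = epsilon,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 weight_decay = weight_decay,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# Convolution and fully connected biases sit immediately before batch
# normalization, which subtracts the batch mean and so cancels them
# exactly; they stay fixed at zero and receive no updates (updating them
# would only let gradient noise random-walk the raw activation scale
# that filter interpretation thresholds against). The output layer has
# no batch norm, so its bias trains normally.
UPDATED_KEYS <- c("W", "gamma", "beta")

rmsprop_init <- function(params) {
  zero_like <- function(layer, keys) {
    out <- list()
    for (k in intersect(keys, names(layer))) out[[k]] <- layer[[k]] * 0
    out
  }
  list(conv = lapply(params$conv, zero_like, keys = UPDATED_KEYS),
       fc = lapply(params$fc, zero_like, keys = UPDATED_KEYS),
       out = zero_like(params$out, c("W", "b")))
}

rmsprop_step <- function(params, grads, state, config) {
  lr <- config$learning_rate
  dc <- config$rmsprop_decay
  eps <- config$epsilon
  wd <- config$weight_decay %||% 0
  upd <- function(p, g, s, decay) {
    if (decay && wd > 0) g <- g + wd * p
    s <- dc * s + (1 - dc) * g * g
    list(p = p - lr * g / (sqrt(s) + eps), s = s)
  }
  for (grp in c("conv", "fc")) {
    for (l in seq_along(grads[[grp]])) {
      for (k in names(state[[grp]][[l]])) {
        r <- upd(params[[grp]][[l]][[k]], grads[[grp]][[l]][[k]],
                 state[[grp]][[l]][[k]], decay = k == "W")
        params[[grp]][[l]][[k]] <- r$p
        state[[grp]][[l]][[k]] <- r$s
      }
    }
  }
  for (k in names(state$out)) {
    r <- upd(params$out[[k]], grads$out[[k]], state$out[[k]],
             decay = k == "W")
    params$out[[k]] <- r$p
    state$out[[k]] <- r$s
  }
  list(params = params, state = state)
}

as_target_matrix <- function(Y) {
  if (is.null(dim(Y))) Y <- matrix(as.numeric(Y), ncol = 1L)
  storage.mode(Y) <- "double"
  Y
}

# One shuffled pass through idx; draws its shuffle and dropout noise from
# the current RNG stream.
run_epoch <- function(model, X, Y, idx, config, state,
                      learning_rate = config$learning_rate) {
  cfg <- config
  cfg$learning_rate <- learning_rate
  ord <- idx[sample.int(length(idx))]
  n_updates <- 0L
  loss_sum <- 0
  for (s in seq(1L, length(ord), by = cfg$batch_size)) {
    take <- ord[s:min(s + cfg$batch_size - 1L, length(ord))]
    Xb <- X[, , take, drop = FALSE]
    Yb <- Y[take, , drop = FALSE]
    fwd <- net_forward(model, Xb, mode = "train", keep_cache = TRUE,
                       update_bn = TRUE)
    model$params <- fwd$params
    loss <- bce_loss_logits(fwd$logits, Yb)
    if (!is.finite(loss)) {
      stop("non-finite training loss at update ", n_updates + 1L,
           "; consider lowering the learning rate (current ",
           cfg$learning_rate, ")")
    }
    grads <- net_backward(model, fwd, Yb)
    stepped <- rmsprop_step(model$params, grads, state, cfg)
    model$params <- stepped$params
    state <- stepped$state
    loss_sum <- loss_sum + loss * length(take)
    n_updates <- n_updates + 1L
  }
  list(model = model, state = state,
       train_loss = loss_sum / length(ord), n_updates = n_updates)
}

validation_metrics <- function(model, X, Y, idx, batch_size) {
  pred <- predict(model, X[, , idx, drop = FALSE], batch_size = batch_size)
  Yv <- Y[idx, , drop = FALSE]
  aucs <- suppressWarnings(
    vapply(seq_len(ncol(Yv)), function(t) auc_score(Yv[, t], pred[, t]),
           numeric(1)))
  list(loss = bce_loss(pred, Yv), auc = mean(aucs, na.rm = TRUE))
}

#' Train the accessibility network
#'
#' Minibatch RMSprop with per-epoch reshuffling, batch-norm running-moment
#' tracking, and early stopping: training halts once the validation loss
#' has not strictly improved for `patience` consecutive epochs (or at
#' `max_epochs`), and the parameters from the best-validation epoch are
#' restored. Fully reproducible given `config$seed`.
#'
#' @param model an `accessnet_model` (or an [architecture_spec()], which
#'   is initialized with a seed derived from `config$seed`).
#' @param data an `accessnet_dataset`, or a list with `X` (4 x L x N
#'   array), `Y` (N x T matrix), and `split` (list with `train` and
#'   `valid` index vectors).
#' @param config a [train_config()].
#' @return an `accessnet_fit`: list with `model` (best-epoch parameters),
#'   `history` (per-epoch train loss, validation loss, validation AUC),
#'   `best_epoch`, and `config`.
#' @export
train_model <- function(model, data, config = train_config()) {
  if (inherits(model, "accessnet_arch")) {
    model <- new_model(model, seed = derive_seed(config$seed, 1))
  }
  stopifnot(inherits(model, "accessnet_model"))
  X <- data$X
  Y <- as_target_matrix(data$Y)
  split <- data$split
  if (is.null(split$train) || is.null(split$valid)) {
    stop("data$split must provide train and valid index vectors")
  }
  if (length(intersect(split$train, split$valid)) > 0L) {
    stop("train and validation sets must be disjoint")
  }
  state <- rmsprop_init(model$params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_loss = numeric(), valid_auc = numeric())
  best <- list(loss = Inf, epoch = 0L, params = model$params)
  stall <- 0L
  with_seed(config$seed, {
    for (epoch in seq_len(config$max_epochs)) {
      ep <- run_epoch(model, X, Y, split$train, config, state)
      model <- ep$model
      state <- ep$state
      vm <- validation_metrics(model, X, Y, split$valid, config$batch_size)
      history[epoch, ] <- list(epoch, ep$train_loss, vm$loss, vm$auc)
      an_message(sprintf("epoch %3d  train %.4f  valid %.4f  auc %.4f",
                         epoch, ep$train_loss, vm$loss, vm$auc),
                 verbose = config$verbose)
      if (vm$loss < best$loss) {
        best <- list(loss = vm$loss, epoch = epoch, params = model$params)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= config$patience) break
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, config = config),
            class = "accessnet_fit")
}

#' @export
print.accessnet_fit <- function(x, ...) {
  h <- x$history
  cat("accessnet_fit:", nrow(h), "epochs, best epoch", x$best_epoch,
      sprintf("(valid loss %.4f, valid AUC %.4f)\n",
              h$valid_loss[x$best_epoch], h$valid_auc[x$best_epoch]))
  invisible(x)
}

#' Seed a new model from a pretrained multi-task model
#'
#' Copies every layer below the output verbatim from the pretrained model
#' (so pre-output representations are identical on any input) and
#' re-initializes only the final linear layer for `n_targets` new
#' targets.
#'
#' @param pretrained an `accessnet_model` or `accessnet_fit`.
#' @param n_targets number of outputs of the new model (typically 1).
#' @param seed seed for the new output layer's weights.
#' @return a new `accessnet_model`.
#' @export
transfer_seed <- function(pretrained, n_targets = 1L, seed = 1L) {
  if (inherits(pretrained, "accessnet_fit")) pretrained <- pretrained$model
  stopifnot(inherits(pretrained, "accessnet_model"))
  spec <- pretrained$spec
  spec$n_targets <- as.integer(n_targets)
  d_in <- ncol(pretrained$params$out$W)
  model <- pretrained
  model$spec <- spec
  model$params$out <- with_seed(seed, list(
    W = matrix(stats::rnorm(n_targets * d_in, sd = 1 / sqrt(d_in)),
               nrow = n_targets),
    b = rep(0, n_targets)))
  model
}

#' One-pass fine-tuning of a seeded model
#'
#' Performs exactly one shuffled epoch of RMSprop updates over the new
#' data at half the configured learning rate, then stops. Additional
#' passes overfit small single-target tasks, so none are taken.
#'
#' @param model an `accessnet_model` (typically from [transfer_seed()]).
#' @param data list with `X` and `Y` (and optionally `split$train`; when
#'   absent, all sequences are used).
#' @param config a [train_config()]; the learning rate actually applied is
#'   `config$learning_rate / 2`.
#' @return list with `model` (updated) and `n_updates`.
#' @export
finetune_single_pass <- function(model, data, config = train_config()) {
  stopifnot(inherits(model, "accessnet_model"))
  X <- data$X
  Y <- as_target_matrix(data$Y)
  idx <- data$split$train %||% seq_len(dim(X)[3])
  if (length(idx) == 0L) return(list(model = model, n_updates = 0L))
  state <- rmsprop_init(model$params)
  with_seed(config$seed, {
    ep <- run_epoch(model, X, Y, idx, config, state,
                    learning_rate = config$learning_rate / 2)
    list(model = ep$model, n_updates = ep$n_updates)
  })
}
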