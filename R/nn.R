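#' @title Network primitives
#'
#' @description
#' The network is built from four primitives: valid (unpadded) 1-D
#' cross-correlation of filter weight matrices against the 4 x L one-hot
#' input, batch normalization, the ReLU rectifier, and non-overlapping
#' max pooling along the spatial axis. Sequence batches are 4 x L x B
#' arrays; convolution activations are C x P x B arrays (filters x
#' positions x sequences).
#'
#' Convolution is implemented by gathering every filter-width window of
#' the input into a column matrix (im2col) so that all positions of all
#' sequences in a batch reduce to a single BLAS matrix product; the
#' gather, pooling and fused batch-norm/ReLU loops are compiled.
#' @name nn_primitives
#' @keywords internal
NULL

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

#' Valid cross-correlation of filters against a one-hot sequence batch
#'
#' Scans each filter (a weight matrix over channels x width) across every
#' position of the input with no padding: output position p is the inner
#' product of the filter with the window starting at p.
#'
#' @param W filter weights, `F x (C*K)` (each row one filter, channel-major
#'   within window position).
#' @param b per-filter biases, length F.
#' @param X input array `C x P x B`.
#' @return list with `Z` (matrix `F x (P_out*B)`, windows position-major
#'   within sequence), `Xcol` (the gathered column matrix), and `P_out`.
#' @export
conv_forward <- function(W, b, X) {
  d <- dim(X)
  K <- as.integer(ncol(W) / d[1])
  if (d[2] < K) stop("input length ", d[2], " shorter than filter width ", K)
  Xcol <- cpp_im2col(X, d[1], d[2], d[3], K)
  Z <- W %*% Xcol + b
  list(Z = Z, Xcol = Xcol, P_out = d[2] - K + 1L, B = d[3])
}

# Batch-norm + ReLU stage as used by the network; Z has one row per
# unit/filter. Returns post-ReLU activations plus backward-pass caches
# (train mode) or just the activations (eval mode).
bn_relu <- function(Z, pp, mode) {
  if (mode == "train") {
    cpp_bn_relu_train(Z, pp$gamma, pp$beta, BN_EPS)
  } else {
    list(A = cpp_bn_relu_eval(Z, pp$gamma, pp$beta, pp$run_mean, pp$run_var,
                              BN_EPS))
  }
}

roll_bn <- function(layer, st) {
  layer$run_mean <- BN_MOMENTUM * layer$run_mean + (1 - BN_MOMENTUM) * st$mu
  layer$run_var <- BN_MOMENTUM * layer$run_var + (1 - BN_MOMENTUM) * st$var
  layer
}

#' Rectified linear unit
#'
#' Elementwise `max(0, x)`.
#'
#' @param x numeric array.
#' @return array of the same shape.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Max pool along the spatial axis
#'
#' Non-overlapping windows of `pool_width` positions; each output is the
#' window maximum. A trailing partial window is kept and pooled over the
#' remaining positions.
#'
#' @param x array `C x P x B` (a plain vector is treated as a single
#'   channel and sequence, a matrix as a single sequence).
#' @param pool_width window size, >= 1.
#' @param want_argmax also return the within-window argmax (used by the
#'   training backward pass).
#' @return pooled array `C x ceiling(P/pool_width) x B`, or a list with
#'   `out` and `arg` when `want_argmax = TRUE`.
#' @export
max_pool <- function(x, pool_width, want_argmax = FALSE) {
  vec_in <- is.null(dim(x))
  if (vec_in) x <- array(x, dim = c(1L, length(x), 1L))
  if (length(dim(x)) == 2L) x <- array(x, dim = c(dim(x), 1L))
  stopifnot(pool_width >= 1)
  d <- dim(x)
  r <- cpp_maxpool_fwd(x, d[1], d[2], d[3], as.integer(pool_width))
  out <- r$out
  dim(out) <- c(d[1], r$n_win, d[3])
  if (want_argmax) {
    arg <- r$arg
    dim(arg) <- dim(out)
    return(list(out = out, arg = arg))
  }
  if (vec_in) return(as.vector(out))
  out
}

max_pool_backward <- function(dOut, arg, P, pool_width) {
  d <- dim(dOut)
  dA <- cpp_maxpool_bwd(dOut, arg, d[1], as.integer(P), d[3],
                        as.integer(pool_width))
  dim(dA) <- c(d[1], P, d[3])
  dA
}

#' Forward pass of the accessibility network
#'
#' Composition per convolution block: convolution, batch normalization
#' (per-filter, spatially shared statistics), ReLU, max pool; then
#' flatten; per fully connected block: linear, batch normalization, ReLU,
#' dropout (train mode only); finally a linear map to `n_targets` logits
#' and a sigmoid. Eval mode uses the stored running batch-norm moments and
#' no dropout, so eval-mode output is a deterministic function of the
#' input.
#'
#' @param model an `accessnet_model`.
#' @param X input: a 4 x L one-hot matrix or a 4 x L x B array.
#' @param mode `"eval"` or `"train"`.
#' @param keep_cache keep intermediate activations for the backward pass.
#' @param nullify optional first-layer filter nullification: a list with
#'   integer `filters` and numeric `values`; the post-ReLU (pre-pool)
#'   activation map of each listed filter is replaced by the matching
#'   constant.
#' @param update_bn update running batch-norm moments (train mode only).
#' @return list with `probs` (B x T matrix of probabilities), `logits`
#'   (T x B), and when requested `cache` and updated `params`.
#' @export
net_forward <- function(model, X, mode = c("eval", "train"),
                        keep_cache = FALSE, nullify = NULL,
                        update_bn = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "accessnet_model"))
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  spec <- model$spec
  if (dim(X)[1] != 4L || dim(X)[2] != spec$input_length) {
    stop("input must be 4 x ", spec$input_length, " x B")
  }
  params <- model$params
  B <- dim(X)[3]
  cache <- list(conv = vector("list", length(spec$conv_layers)),
                fc = vector("list", length(spec$fc_layers)))
  cur <- X
  for (l in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[l]]
    pp <- params$conv[[l]]
    in_dim <- dim(cur)
    cv <- conv_forward(pp$W, pp$b, cur)
    st <- bn_relu(cv$Z, pp, mode)
    if (update_bn && mode == "train") {
      params$conv[[l]] <- roll_bn(params$conv[[l]], st)
    }
    A <- st$A
    dim(A) <- c(cl$n_filters, cv$P_out, B)
    if (l == 1L && !is.null(nullify)) {
      for (i in seq_along(nullify$filters)) {
        A[nullify$filters[i], , ] <- nullify$values[i]
      }
    }
    pl <- max_pool(A, cl$pool_width, want_argmax = keep_cache)
    if (keep_cache) {
      cache$conv[[l]] <- list(Xcol = cv$Xcol, zhat = st$zhat,
                              inv_sd = st$inv_sd, A = st$A,
                              P_out = cv$P_out, arg = pl$arg,
                              in_dim = in_dim)
      cur <- pl$out
    } else {
      cur <- pl
    }
  }
  d <- dim(cur)
  dim(cur) <- c(d[1] * d[2], d[3])
  conv_out_dim <- d
  for (l in seq_along(spec$fc_layers)) {
    pp <- params$fc[[l]]
    Z <- pp$W %*% cur + pp$b
    st <- bn_relu(Z, pp, mode)
    if (update_bn && mode == "train") {
      params$fc[[l]] <- roll_bn(params$fc[[l]], st)
    }
    A <- st$A
    mask_scaled <- NULL
    if (mode == "train" && spec$dropout[l] > 0) {
      keep <- 1 - spec$dropout[l]
      mask_scaled <- matrix((stats::runif(length(A)) < keep) / keep,
                            nrow = nrow(A))
      A2 <- A * mask_scaled
    } else {
      A2 <- A
    }
    if (keep_cache) {
      cache$fc[[l]] <- list(input = cur, zhat = st$zhat, inv_sd = st$inv_sd,
                            A = A, mask_scaled = mask_scaled)
    }
    cur <- A2
  }
  logits <- params$out$W %*% cur + params$out$b
  probs <- stats::plogis(logits)
  res <- list(probs = t(probs), logits = logits)
  if (keep_cache) {
    cache$fc_out_input <- cur
    cache$conv_out_dim <- conv_out_dim
    res$cache <- cache
  }
  if (update_bn) res$params <- params
  res
}

#' Binary cross-entropy loss, summed over targets, averaged over the batch
#'
#' `-sum_t [y log p + (1 - y) log(1 - p)]` per sequence (natural log),
#' then the mean over the batch.
#'
#' @param pred B x T matrix of probabilities in (0,1).
#' @param target B x T binary matrix (or vector for T = 1).
#' @return scalar loss.
#' @export
bce_loss <- function(pred, target) {
  pred <- as.matrix(pred)
  target <- matrix(as.numeric(target), nrow = nrow(pred))
  stopifnot(all(dim(pred) == dim(target)))
  eps <- 1e-12
  p <- pmin(pmax(pred, eps), 1 - eps)
  -mean(rowSums(target * log(p) + (1 - target) * log(1 - p)))
}

# Numerically stable loss straight from logits (T x B) and targets (B x T).
bce_loss_logits <- function(logits, target) {
  y <- t(matrix(as.numeric(target), ncol = nrow(logits)))
  mean(colSums(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits)))))
}

#' Backward pass: gradients of the loss with respect to all parameters
#'
#' Backpropagates the batch-averaged binary cross entropy through the
#' network using the cache produced by a train-mode forward pass
#' (`keep_cache = TRUE`). Train-mode batch-norm statistics are part of the
#' graph and are differentiated exactly.
#'
#' @param model the model used for the forward pass.
#' @param fwd result of `net_forward(..., mode = "train", keep_cache = TRUE)`.
#' @param Y B x T binary target matrix.
#' @return list of gradients mirroring `model$params` (weights, biases and
#'   batch-norm scale/shift; running moments carry no gradient).
#' @keywords internal
net_backward <- function(model, fwd, Y) {
  spec <- model$spec
  params <- model$params
  cache <- fwd$cache
  B <- nrow(fwd$probs)
  grads <- list(conv = vector("list", length(spec$conv_layers)),
                fc = vector("list", length(spec$fc_layers)))
  dlogits <- (t(fwd$probs) - t(matrix(as.numeric(Y), nrow = B))) / B
  grads$out <- list(W = tcrossprod(dlogits, cache$fc_out_input),
                    b = rowSums(dlogits))
  dcur <- crossprod(params$out$W, dlogits)
  for (l in rev(seq_along(spec$fc_layers))) {
    cc <- cache$fc[[l]]
    if (!is.null(cc$mask_scaled)) dcur <- dcur * cc$mask_scaled
    bnb <- cpp_bn_relu_bwd(dcur, cc$A, cc$zhat, cc$inv_sd,
                           params$fc[[l]]$gamma)
    grads$fc[[l]] <- list(W = tcrossprod(bnb$dZ, cc$input),
                          b = rowSums(bnb$dZ),
                          gamma = bnb$dgamma, beta = bnb$dbeta)
    dcur <- crossprod(params$fc[[l]]$W, bnb$dZ)
  }
  dim(dcur) <- cache$conv_out_dim
  for (l in rev(seq_along(spec$conv_layers))) {
    cl <- spec$conv_layers[[l]]
    cc <- cache$conv[[l]]
    dA <- max_pool_backward(dcur, cc$arg, cc$P_out, cl$pool_width)
    dim(dA) <- c(cl$n_filters, cc$P_out * B)
    bnb <- cpp_bn_relu_bwd(dA, cc$A, cc$zhat, cc$inv_sd,
                           params$conv[[l]]$gamma)
    grads$conv[[l]] <- list(W = tcrossprod(bnb$dZ, cc$Xcol),
                            b = rowSums(bnb$dZ),
                            gamma = bnb$dgamma, beta = bnb$dbeta)
    if (l > 1L) {
      dXcol <- crossprod(params$conv[[l]]$W, bnb$dZ)
      in_dim <- cc$in_dim
      dcur <- cpp_col2im(dXcol, in_dim[1], in_dim[2], in_dim[3],
                         cl$filter_width)
      dim(dcur) <- in_dim
    }
  }
  grads
}

#' Predict accessibility probabilities for a batch of sequences
#'
#' Runs the network in eval mode (running batch-norm moments, no dropout)
#' over `X` in chunks.
#'
#' @param object an `accessnet_model`.
#' @param X 4 x L x B array (or a single 4 x L matrix).
#' @param batch_size chunk size for the forward passes.
#' @param nullify optional filter nullification, see [net_forward()].
#' @param ... unused.
#' @return B x T matrix of probabilities.
#' @export
predict.accessnet_model <- function(object, X, batch_size = 256L,
                                    nullify = NULL, ...) {
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  B <- dim(X)[3]
  out <- matrix(NA_real_, nrow = B, ncol = object$spec$n_targets)
  for (s in seq(1L, B, by = batch_size)) {
    e <- min(s + batch_size - 1L, B)
    out[s:e, ] <- net_forward(object, X[, , s:e, drop = FALSE],
                              mode = "eval", nullify = nullify)$probs
  }
  out
}
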