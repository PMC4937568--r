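# Independent reference implementations used as oracles. These
# deliberately recompute everything from scratch with naive loops and
# share no code with the package internals.

# Greedy peak merging, recomputing the closest-overlapping adjacent pair
# from a full re-sort at every step.
merge_oracle <- function(peaks, width, overlap_bound) {
  chroms <- split(seq_len(nrow(peaks)), peaks$chrom)
  res <- list()
  for (ch in names(chroms)) {
    rows <- chroms[[ch]]
    mids <- peaks$start[rows] + width %/% 2L
    wts <- if (is.null(peaks$weight)) {
      vapply(peaks$cells[rows], length, 1L)
    } else {
      peaks$weight[rows]
    }
    cells <- peaks$cells[rows]
    repeat {
      ord <- order(mids)
      mids <- mids[ord]; wts <- wts[ord]; cells <- cells[ord]
      if (length(mids) <= 1L) break
      best_i <- NA; best_ov <- -Inf
      for (i in seq_len(length(mids) - 1L)) {
        ov <- width - (mids[i + 1L] - mids[i])
        if (ov > best_ov) { best_ov <- ov; best_i <- i }
      }
      if (best_ov <= overlap_bound) break
      i <- best_i
      new_mid <- floor((wts[i] * mids[i] + wts[i + 1] * mids[i + 1]) /
                         (wts[i] + wts[i + 1]) + 0.5)
      new_cells <- union(cells[[i]], cells[[i + 1]])
      new_wt <- wts[i] + wts[i + 1]
      keep <- setdiff(seq_along(mids), c(i, i + 1L))
      mids <- c(mids[keep], new_mid)
      wts <- c(wts[keep], new_wt)
      cells <- c(cells[keep], list(new_cells))
    }
    ord <- order(mids)
    res[[ch]] <- data.frame(chrom = ch, start = mids[ord] - width %/% 2L,
                            end = mids[ord] - width %/% 2L + width,
                            cells = I(cells[ord]), weight = wts[ord])
  }
  out <- do.call(rbind, res[order(names(res))])
  rownames(out) <- NULL
  out
}

# AUC by exhaustive positive/negative pair counting.
auc_pair_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# AUPRC by an explicit walk over every distinct threshold, counting TP
# and predicted positives by brute force at each.
auprc_oracle <- function(labels, scores) {
  th <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  n_pos <- sum(labels == 1)
  for (t in th) {
    sel <- scores >= t
    tp <- sum(labels == 1 & sel)
    prec <- tp / sum(sel)
    rec <- tp / n_pos
    area <- area + (rec - prev_recall) * prec
    prev_recall <- rec
  }
  area
}

recall_at_fpr_oracle <- function(labels, scores, fpr_bound) {
  th <- sort(unique(scores), decreasing = TRUE)
  best <- 0
  for (t in th) {
    sel <- scores >= t
    fpr <- sum(labels == 0 & sel) / sum(labels == 0)
    tpr <- sum(labels == 1 & sel) / sum(labels == 1)
    if (fpr <= fpr_bound) best <- max(best, tpr)
  }
  best
}

# Naive eval-mode forward pass: explicit loops over filters, positions
# and units, composing convolution -> batch norm (running moments) ->
# ReLU -> max pool -> fully connected -> sigmoid.
naive_forward <- function(model, xmat) {
  eps <- 1e-5
  spec <- model$spec
  cur <- xmat                          # channels x positions
  for (l in seq_along(spec$conv_layers)) {
    cl <- spec$conv_layers[[l]]
    pp <- model$params$conv[[l]]
    C <- nrow(cur); P <- ncol(cur); K <- cl$filter_width
    P_out <- P - K + 1
    act <- matrix(0, cl$n_filters, P_out)
    for (f in seq_len(cl$n_filters)) {
      wf <- matrix(pp$W[f, ], nrow = C)  # C x K, channel-major
      for (p in seq_len(P_out)) {
        z <- sum(wf * cur[, p:(p + K - 1)]) + pp$b[f]
        z <- pp$gamma[f] * (z - pp$run_mean[f]) /
          sqrt(pp$run_var[f] + eps) + pp$beta[f]
        act[f, p] <- max(0, z)
      }
    }
    n_win <- ceiling(P_out / cl$pool_width)
    pooled <- matrix(0, cl$n_filters, n_win)
    for (w in seq_len(n_win)) {
      cols <- ((w - 1) * cl$pool_width + 1):min(w * cl$pool_width, P_out)
      pooled[, w] <- apply(act[, cols, drop = FALSE], 1, max)
    }
    cur <- pooled
  }
  v <- as.vector(cur)
  for (l in seq_along(spec$fc_layers)) {
    pp <- model$params$fc[[l]]
    z <- as.vector(pp$W %*% v + pp$b)
    z <- pp$gamma * (z - pp$run_mean) / sqrt(pp$run_var + eps) + pp$beta
    v <- pmax(0, z)
  }
  z <- as.vector(model$params$out$W %*% v + model$params$out$b)
  1 / (1 + exp(-z))
}

# Random peak sets for merge fuzzing.
random_peak_set <- function(n, width = 600L, n_chrom = 2L) {
  chrom <- sort(sample(paste0("chr", seq_len(n_chrom)), n, replace = TRUE))
  mid <- width %/% 2L + sample.int(5L * width, n, replace = TRUE)
  start <- mid - width %/% 2L
  df <- data.frame(chrom = chrom, start = start, end = start + width,
                   stringsAsFactors = FALSE)
  df$cells <- lapply(seq_len(n), function(i) {
    sample(letters[1:6], sample.int(3L, 1L))
  })
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, TRUE),
                                collapse = "")

# A small randomly initialized model whose batch-norm running moments are
# perturbed away from the 0/1 defaults so eval mode exercises them.
random_eval_model <- function(spec, seed = 1) {
  m <- new_model(spec, seed = seed)
  set.seed(seed + 1000)
  for (l in seq_along(m$params$conv)) {
    n <- length(m$params$conv[[l]]$run_mean)
    m$params$conv[[l]]$run_mean <- rnorm(n, 0, 0.3)
    m$params$conv[[l]]$run_var <- runif(n, 0.5, 1.5)
  }
  for (l in seq_along(m$params$fc)) {
    n <- length(m$params$fc[[l]]$run_mean)
    m$params$fc[[l]]$run_mean <- rnorm(n, 0, 0.3)
    m$params$fc[[l]]$run_var <- runif(n, 0.5, 1.5)
  }
  m
}
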