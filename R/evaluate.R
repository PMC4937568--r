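#' Area under the ROC curve (rank statistic, midrank ties)
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counted half — equivalently the normalized
#' Mann-Whitney U computed from midranks. Undefined (NA, with a warning)
#' when only one class is present.
#'
#' @param labels binary vector (0/1 or logical).
#' @param scores numeric vector of the same length.
#' @return AUC in \[0, 1\], or `NA` for single-class labels.
#' @export
auc_score <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores)                       # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Precision/recall at every distinct score threshold, most permissive
# last. Returns one row per threshold (score groups with ties collapsed).
pr_points <- function(labels, scores) {
  labels <- as.numeric(labels)
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  grp_end <- which(c(sc[-1] != sc[-length(sc)], TRUE))
  tp <- cumsum(lab)[grp_end]
  n_pred <- grp_end
  data.frame(threshold = sc[grp_end], tp = tp, n_pred = n_pred,
             precision = tp / n_pred, recall = tp / sum(labels),
             fpr = (n_pred - tp) / sum(labels == 0))
}

#' Area under the precision-recall curve
#'
#' Step-wise interpolation over the distinct score thresholds:
#' `sum_k (R_k - R_{k-1}) * P_k` walking thresholds from strictest to most
#' permissive. Undefined (NA, with a warning) without positives.
#'
#' @inheritParams auc_score
#' @return AUPRC, or `NA` when no positives are present.
#' @export
auprc_score <- function(labels, scores) {
  labels <- as.numeric(labels)
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  if (sum(labels) == 0) {
    warning("AUPRC undefined: no positive labels")
    return(NA_real_)
  }
  pts <- pr_points(labels, scores)
  sum(diff(c(0, pts$recall)) * pts$precision)
}

#' Recall at a bounded false-positive rate
#'
#' True-positive rate at the most permissive threshold whose
#' false-positive rate does not exceed `fpr`.
#'
#' @inheritParams auc_score
#' @param fpr false-positive-rate bound (default 0.10).
#' @return recall in \[0, 1\].
#' @export
recall_at_fpr <- function(labels, scores, fpr = 0.1) {
  labels <- as.numeric(labels)
  if (sum(labels == 1) == 0L || sum(labels == 0) == 0L) {
    warning("recall_at_fpr undefined: only one class present")
    return(NA_real_)
  }
  pts <- pr_points(labels, scores)
  ok <- pts$fpr <= fpr
  if (!any(ok)) return(0)
  max(pts$recall[ok])
}

#' Recall at a bounded false-discovery rate
#'
#' True-positive rate at the most permissive threshold whose false
#' discovery rate (1 - precision) does not exceed `fdr`.
#'
#' @inheritParams auc_score
#' @param fdr false-discovery-rate bound (default 0.20).
#' @return recall in \[0, 1\].
#' @export
recall_at_fdr <- function(labels, scores, fdr = 0.2) {
  labels <- as.numeric(labels)
  if (sum(labels == 1) == 0L) {
    warning("recall_at_fdr undefined: no positives")
    return(NA_real_)
  }
  pts <- pr_points(labels, scores)
  ok <- (1 - pts$precision) <= fdr
  if (!any(ok)) return(0)
  max(pts$recall[ok])
}

#' ROC curve points
#'
#' False-positive rate and true-positive rate at every distinct score
#' threshold (no binning), from strictest to most permissive, with the
#' (0,0) origin prepended.
#'
#' @inheritParams auc_score
#' @return data.frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(labels, scores) {
  pts <- pr_points(labels, scores)
  data.frame(threshold = c(Inf, pts$threshold),
             fpr = c(0, pts$fpr), tpr = c(0, pts$recall))
}

#' Multi-label accuracy report for a trained model
#'
#' Per-cell ROC AUC and AUPRC on the requested index set, with means over
#' the cells where the metric is defined (cells missing a class in the
#' evaluation split are reported as NA and excluded from means).
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param data an `accessnet_dataset` (or list with `X`, `Y`).
#' @param idx indices of sites to evaluate (default: the dataset's test
#'   split).
#' @param curves also keep per-cell ROC points.
#' @return an `accessnet_eval`: list with `per_cell` (data.frame: cell,
#'   auc, auprc, recall at FPR 0.10, recall at FDR 0.20), `mean_auc`,
#'   `mean_auprc`, and optionally `roc`.
#' @export
evaluate_model <- function(model, data, idx = data$split$test, curves = FALSE) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  Y <- as_target_matrix(data$Y)
  if (is.null(idx) || length(idx) == 0L) idx <- seq_len(nrow(Y))
  pred <- predict(model, data$X[, , idx, drop = FALSE])
  Yt <- Y[idx, , drop = FALSE]
  cells <- data$cells %||% colnames(Yt) %||% paste0("cell", seq_len(ncol(Yt)))
  per_cell <- do.call(rbind, lapply(seq_len(ncol(Yt)), function(t) {
    suppressWarnings(data.frame(
      cell = cells[t],
      auc = auc_score(Yt[, t], pred[, t]),
      auprc = auprc_score(Yt[, t], pred[, t]),
      recall_fpr10 = recall_at_fpr(Yt[, t], pred[, t], 0.1),
      recall_fdr20 = recall_at_fdr(Yt[, t], pred[, t], 0.2)))
  }))
  out <- list(per_cell = per_cell,
              mean_auc = mean(per_cell$auc, na.rm = TRUE),
              mean_auprc = mean(per_cell$auprc, na.rm = TRUE),
              n_sites = length(idx))
  if (curves) {
    out$roc <- lapply(seq_len(ncol(Yt)), function(t) {
      suppressWarnings(roc_points(Yt[, t], pred[, t]))
    })
    names(out$roc) <- cells
  }
  structure(out, class = "accessnet_eval")
}

#' @export
print.accessnet_eval <- function(x, ...) {
  cat(sprintf("accessnet_eval on %d sites: mean AUC %.3f, mean AUPRC %.3f\n",
              x$n_sites, x$mean_auc, x$mean_auprc))
  print(x$per_cell, row.names = FALSE, digits = 3)
  invisible(x)
}
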