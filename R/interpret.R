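#' @title Model interpretation
#'
#' @description
#' The first convolution layer scans the sequence with pattern
#' recognizers that play the role position weight matrices play in
#' classical motif analysis. These functions distill each filter into a
#' probabilistic PWM by counting nucleotides in the subsequences that
#' activate the filter above half of its maximum, quantify the
#' information content of such PWMs, measure each filter's influence on
#' the cell predictions by nullifying its activation map, and probe the
#' trained model by inserting motifs into sequences.
#' @name interpretation
NULL

# Raw first-layer filter activations (convolution output before batch
# normalization) for a set of sequences; F x P_out x B.
conv1_raw_activations <- function(model, X, batch_size = 256L) {
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  pp <- model$params$conv[[1]]
  K <- model$spec$conv_layers[[1]]$filter_width
  B <- dim(X)[3]
  P_out <- dim(X)[2] - K + 1L
  out <- array(NA_real_, dim = c(nrow(pp$W), P_out, B))
  for (s in seq(1L, B, by = batch_size)) {
    e <- min(s + batch_size - 1L, B)
    cv <- conv_forward(pp$W, pp$b, X[, , s:e, drop = FALSE])
    out[, , s:e] <- array(cv$Z, dim = c(nrow(pp$W), P_out, e - s + 1L))
  }
  out
}

# Post-ReLU first-layer activation maps as seen by the rest of the
# network (convolution -> batch norm in eval mode -> ReLU).
conv1_network_activations <- function(model, X, batch_size = 256L) {
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  pp <- model$params$conv[[1]]
  K <- model$spec$conv_layers[[1]]$filter_width
  B <- dim(X)[3]
  P_out <- dim(X)[2] - K + 1L
  out <- array(NA_real_, dim = c(nrow(pp$W), P_out, B))
  for (s in seq(1L, B, by = batch_size)) {
    e <- min(s + batch_size - 1L, B)
    cv <- conv_forward(pp$W, pp$b, X[, , s:e, drop = FALSE])
    A <- cpp_bn_relu_eval(cv$Z, pp$gamma, pp$beta, pp$run_mean, pp$run_var,
                          BN_EPS)
    out[, , s:e] <- array(A, dim = c(nrow(pp$W), P_out, e - s + 1L))
  }
  out
}

#' Distill a first-layer filter into a position weight matrix
#'
#' Scans the filter over every sequence, collects each filter-width
#' subsequence whose raw activation exceeds half of the filter's maximum
#' activation over the whole set, and tabulates position-wise nucleotide
#' frequencies over that collection (each supporting subsequence counted
#' once). A pseudocount of 1 in total (0.25 per nucleotide) per position
#' keeps the PWM defined under few supports. A filter that never
#' activates above zero is a dead filter: the function warns and returns
#' `NULL`.
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param filter_id first-layer filter index.
#' @param X 4 x L x B array of (typically held-out) sequences.
#' @param background length-4 background nucleotide probabilities used for
#'   the information content.
#' @param activations optional precomputed [conv1_raw_activations()]
#'   array, to avoid rescanning when distilling many filters.
#' @return a `filter_pwm`: list with `pwm` (W x 4 matrix, columns
#'   A,C,G,T), `background`, `ic` (bits), `n_supporting`, `filter_id`.
#' @export
filter_to_pwm <- function(model, filter_id, X, background = rep(0.25, 4),
                          activations = NULL) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  stopifnot(dim(X)[3] >= 1)
  W <- model$spec$conv_layers[[1]]$filter_width
  if (is.null(activations)) activations <- conv1_raw_activations(model, X)
  act <- activations[filter_id, , , drop = FALSE]
  gmax <- max(act)
  if (gmax <= 0) {
    warning("dead filter ", filter_id, ": maximum activation <= 0, no PWM")
    return(NULL)
  }
  hits <- which(act > gmax / 2, arr.ind = TRUE)   # cols: 1, position, seq
  counts <- matrix(0, nrow = 4L, ncol = W,
                   dimnames = list(c("A", "C", "G", "T"), NULL))
  for (h in seq_len(nrow(hits))) {
    p <- hits[h, 2]
    counts <- counts + X[, p:(p + W - 1L), hits[h, 3]]
  }
  counts <- counts + 0.25
  pwm <- t(counts) / colSums(counts)
  colnames(pwm) <- c("A", "C", "G", "T")
  structure(list(pwm = pwm, background = background,
                 ic = information_content(pwm, background),
                 n_supporting = nrow(hits), filter_id = filter_id),
            class = "filter_pwm")
}

#' @export
print.filter_pwm <- function(x, ...) {
  cat(sprintf("filter_pwm %s: width %d, IC %.2f bits, %d supports, consensus %s\n",
              x$filter_id %||% "?", nrow(x$pwm), x$ic, x$n_supporting,
              pwm_consensus(x$pwm)))
  invisible(x)
}

#' Information content of a motif in bits
#'
#' `IC = -sum_(i,j) b_j log2 b_j + sum_(i,j) m_ij log2 m_ij`, with the
#' background term added once per motif position and `0 * log2(0)` taken
#' as 0. For a uniform background this is at most 2 bits per position.
#'
#' @param m W x 4 matrix of nucleotide probabilities (rows sum to 1).
#' @param b length-4 background probabilities.
#' @return information content in bits.
#' @export
information_content <- function(m, b = rep(0.25, 4)) {
  if (inherits(m, "filter_pwm")) m <- m$pwm
  stopifnot(ncol(m) == 4L, length(b) == 4L)
  xlx <- function(p) ifelse(p > 0, p * log2(p), 0)
  -nrow(m) * sum(xlx(b)) + sum(xlx(m))
}

#' Score every first-layer filter's influence by nullification
#'
#' For each filter, computes its scalar mean post-ReLU activation over
#' all positions of all supplied sequences, replaces the filter's whole
#' activation map by that constant (blocking any information flow through
#' it, including positional information), and re-runs the forward pass.
#' The influence of the filter is the sum of squares of the per-cell
#' changes in mean predicted accessibility.
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param X 4 x L x B array of test sequences.
#' @param filters which first-layer filters to score (default all).
#' @return an `influence_table` data.frame: `filter`, `influence`, and one
#'   `delta_<cell>` column per target with the mean prediction change
#'   (original minus nullified).
#' @export
filter_influence <- function(model, X, filters = NULL) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  n_f <- model$spec$conv_layers[[1]]$n_filters
  if (is.null(filters)) filters <- seq_len(n_f)
  acts <- conv1_network_activations(model, X)
  fmeans <- apply(acts, 1L, mean)
  orig <- colMeans(predict(model, X))
  rows <- lapply(filters, function(f) {
    np <- colMeans(predict(model, X,
                           nullify = list(filters = f, values = fmeans[f])))
    delta <- orig - np
    c(filter = f, influence = sum(delta^2), delta)
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("filter", "influence",
                  paste0("delta_", seq_len(length(orig))))
  class(out) <- c("influence_table", "data.frame")
  out
}

#' Cluster filters by their influence profiles
#'
#' Hierarchical clustering (Euclidean distance, average linkage) of the
#' per-cell prediction-change vectors, grouping filters that act on the
#' same cell types.
#'
#' @param influence an `influence_table` from [filter_influence()].
#' @return an [stats::hclust] object.
#' @export
cluster_filters <- function(influence) {
  m <- as.matrix(influence[, grep("^delta_", names(influence)), drop = FALSE])
  rownames(m) <- influence$filter
  stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
}

#' Predicted effect of inserting a motif into sequence centers
#'
#' Replaces the central W bases of every sequence with the motif (its
#' consensus, or per-sequence samples from the PWM) and returns the
#' change in predicted accessibility, after minus before, per sequence
#' and cell.
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param motif a W x 4 PWM (columns A,C,G,T), a `filter_pwm`, or a
#'   consensus DNA string.
#' @param X 4 x L x B array of sequences to probe.
#' @param sample_from_pwm sample one motif instance per sequence from the
#'   PWM instead of inserting the consensus.
#' @param seed seed for PWM sampling.
#' @return B x T matrix of prediction deltas.
#' @export
motif_insertion_effect <- function(model, motif, X, sample_from_pwm = FALSE,
                                   seed = 1L) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  if (inherits(motif, "filter_pwm")) motif <- motif$pwm
  if (length(dim(X)) == 2L) dim(X) <- c(dim(X), 1L)
  L <- dim(X)[2]
  B <- dim(X)[3]
  if (is.character(motif)) motif_mat <- one_hot_encode(motif) else {
    stopifnot(is.matrix(motif), ncol(motif) == 4L)
    motif_mat <- NULL
  }
  W <- if (is.null(motif_mat)) nrow(motif) else ncol(motif_mat)
  if (W > L) stop("motif width ", W, " exceeds sequence length ", L)
  start <- (L - W) %/% 2L + 1L
  X2 <- X
  if (is.null(motif_mat) && !sample_from_pwm) {
    motif_mat <- one_hot_encode(pwm_consensus(motif))
  }
  if (sample_from_pwm) {
    if (!is.matrix(motif)) stop("sampling requires a PWM, not a consensus string")
    bases <- with_seed(seed, vapply(seq_len(B), function(i) {
      paste(apply(motif, 1L, function(p) sample(c("A", "C", "G", "T"), 1L,
                                                prob = p)),
            collapse = "")
    }, ""))
    for (i in seq_len(B)) {
      X2[, start:(start + W - 1L), i] <- one_hot_encode(bases[i])
    }
  } else {
    for (i in seq_len(B)) X2[, start:(start + W - 1L), i] <- motif_mat
  }
  predict(model, X2) - predict(model, X)
}

#' Write motifs in MEME minimal format
#'
#' Emits a MEME version 4 minimal motif file (background frequency line,
#' one letter-probability matrix per motif with `nsites` set to the
#' number of supporting subsequences), suitable as query input for motif
#' comparison tools such as TomTom against databases such as CIS-BP.
#'
#' @param pwms a `filter_pwm` or list of them (`NULL` entries from dead
#'   filters are skipped).
#' @param path output file.
#' @param background length-4 background probabilities written to the
#'   header.
#' @return invisibly, `path`.
#' @export
write_meme <- function(pwms, path, background = rep(0.25, 4)) {
  if (inherits(pwms, "filter_pwm")) pwms <- list(pwms)
  pwms <- Filter(Negate(is.null), pwms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f", background[1],
                       background[2], background[3], background[4]), ""),
             con)
  for (p in pwms) {
    id <- p$filter_id %||% "motif"
    writeLines(sprintf("MOTIF filter_%s", id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       nrow(p$pwm), max(1L, p$n_supporting)), con)
    writeLines(apply(p$pwm, 1L, function(r) sprintf("%.6f %.6f %.6f %.6f",
                                                    r[1], r[2], r[3], r[4])),
               con)
    writeLines("", con)
  }
  invisible(path)
}

#' Best alignment of one PWM against another by total-variation distance
#'
#' Slides the shorter motif along the longer (both orientations unless
#' `include_rc = FALSE`) and reports the offset minimizing the mean
#' per-position total-variation distance, `0.5 * sum_j |m1_ij - m2_ij|`
#' averaged over the overlap (the shorter motif's full width).
#'
#' @param query,target W x 4 PWMs (columns A,C,G,T); `filter_pwm` objects
#'   are accepted.
#' @param include_rc also consider the reverse complement of `query`.
#' @return list with `tvd` (best mean per-position TVD), `offset` (0-based
#'   start of the shorter motif within the longer), `strand` (`"+"` or
#'   `"-"` orientation of the query), `flipped` (TRUE when the target was
#'   the shorter motif).
#' @export
pwm_match_tvd <- function(query, target, include_rc = TRUE) {
  if (inherits(query, "filter_pwm")) query <- query$pwm
  if (inherits(target, "filter_pwm")) target <- target$pwm
  stopifnot(ncol(query) == 4L, ncol(target) == 4L)
  orientations <- list(`+` = query)
  if (include_rc) orientations$`-` <- reverse_complement_pwm(query)
  best <- list(tvd = Inf, offset = NA_integer_, strand = NA_character_,
               flipped = NA)
  for (st in names(orientations)) {
    q <- orientations[[st]]
    flip <- nrow(q) > nrow(target)
    short <- if (flip) target else q
    long <- if (flip) q else target
    for (off in 0:(nrow(long) - nrow(short))) {
      seg <- long[off + seq_len(nrow(short)), , drop = FALSE]
      tvd <- mean(0.5 * rowSums(abs(short - seg)))
      if (tvd < best$tvd) {
        best <- list(tvd = tvd, offset = off, strand = st, flipped = flip)
      }
    }
  }
  best
}
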