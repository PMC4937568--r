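#' @title Peak harmonization: fixed-width sites with a binary activity matrix
#'
#' @description
#' Accessibility peak calls arrive as one BED file per cell type, with
#' heterogeneous widths and heavily overlapping intervals across cells.
#' The functions here reduce them to a single non-redundant set of
#' fixed-width sites: every peak is extended to a common width around its
#' midpoint, then overlapping peaks are greedily merged (closest pair
#' first) until no two adjacent sites overlap by more than a bound, the
#' merged site inheriting the union of active cell types and a midpoint
#' weighted by how many cells each parent was active in.
#'
#' Coordinates are BED-style throughout: 0-based, half-open.
#' @name peaks_prep
NULL

#' Read a BED file of peaks
#'
#' Reads the first three columns (chrom, start, end) of a BED file; any
#' further columns are ignored. Coordinates are kept 0-based half-open.
#'
#' @param path BED file path.
#' @param cell optional cell-type label attached to every peak.
#' @return data.frame with columns `chrom`, `start`, `end` and, when
#'   `cell` is given, a list-column `cells`.
#' @export
read_bed_peaks <- function(path, cell = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE, fill = TRUE,
                          stringsAsFactors = FALSE)[, 1:3]
  df[[1]] <- as.character(df[[1]])
  names(df) <- c("chrom", "start", "end")
  if (any(df$start >= df$end)) stop("BED intervals must satisfy start < end")
  if (!is.null(cell)) df$cells <- replicate(nrow(df), cell, simplify = FALSE)
  df
}

#' Extend peaks to a fixed width around their midpoints
#'
#' Each interval is replaced by one of width `width` centered on its
#' integer midpoint (`floor((start + end) / 2)`); the new start is
#' `midpoint - floor(width / 2)`. Peaks whose extension would run past the
#' chromosome start are flagged as edge peaks and, depending on
#' `edge_policy`, dropped or clipped to `[0, width)`.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally a `cells` list-column.
#' @param width target width in bp (default 600).
#' @param edge_policy `"drop"` (default) or `"clip"` for peaks that would
#'   extend below position 0.
#' @return data.frame of extended peaks with a logical `edge` column.
#' @export
extend_peaks <- function(peaks, width = 600L, edge_policy = c("drop", "clip")) {
  edge_policy <- match.arg(edge_policy)
  stopifnot(is.data.frame(peaks), width > 0)
  mid <- floor((peaks$start + peaks$end) / 2)
  start <- mid - width %/% 2L
  end <- start + width
  edge <- start < 0
  out <- peaks
  out$start <- start
  out$end <- end
  out$edge <- edge
  if (any(edge)) {
    if (edge_policy == "drop") {
      warning(sum(edge), " edge peak(s) dropped (extension below position 0)")
      out <- out[!edge, , drop = FALSE]
    } else {
      out$start[edge] <- 0
      out$end[edge] <- width
    }
  }
  rownames(out) <- NULL
  out
}

peak_midpoints <- function(peaks, width) peaks$start + width %/% 2L

#' Greedily merge overlapping fixed-width peaks
#'
#' Within each chromosome, repeatedly finds the adjacent pair of peaks
#' with the largest overlap and, while that overlap exceeds
#' `overlap_bound`, replaces the pair with a single peak whose midpoint is
#' the weight-averaged midpoint `floor((w1*m1 + w2*m2)/(w1+w2) + 0.5)`,
#' whose activity is the union of the parents' active cell sets, and whose
#' weight is the sum of the parents' weights. When two pairs tie on
#' overlap the leftmost pair merges first. Iteration continues to
#' convergence, so on return no two adjacent peaks overlap by more than
#' `overlap_bound`.
#'
#' @param peaks data.frame of uniform-width peaks with columns `chrom`,
#'   `start`, `end`, a list-column `cells` (character vectors of active
#'   cell types), and optionally `weight` (defaults to the number of
#'   active cells per peak). Must be sorted by start within chromosome.
#' @param width the common peak width in bp.
#' @param overlap_bound merge peaks while adjacent overlap exceeds this
#'   many bp (default 200).
#' @return data.frame of merged peaks (`chrom`, `start`, `end`, `cells`,
#'   `weight`), sorted by chromosome and start.
#' @export
merge_peaks <- function(peaks, width = 600L, overlap_bound = 200L) {
  stopifnot(is.data.frame(peaks), !is.null(peaks$cells))
  if (nrow(peaks) == 0L) return(peaks)
  if (!all(peaks$end - peaks$start == width)) {
    stop("peaks must all have the target width; run extend_peaks() first")
  }
  ord_ok <- unsplit(lapply(split(peaks$start, peaks$chrom), function(s) {
    if (length(s) <= 1L) TRUE else c(TRUE, diff(s) >= 0)
  }), peaks$chrom)
  if (!all(ord_ok)) stop("peaks must be sorted by start within each chromosome")
  if (is.null(peaks$weight)) peaks$weight <- vapply(peaks$cells, length, 1L)

  merged <- lapply(split(peaks, peaks$chrom), function(df) {
    mid <- as.numeric(peak_midpoints(df, width))
    wt <- as.numeric(df$weight)
    cells <- df$cells
    repeat {
      if (length(mid) <= 1L) break
      ov <- width - diff(mid)
      i <- which.max(ov)            # leftmost maximal pair on ties
      if (ov[i] <= overlap_bound) break
      new_mid <- floor((wt[i] * mid[i] + wt[i + 1L] * mid[i + 1L]) /
                         (wt[i] + wt[i + 1L]) + 0.5)
      new_wt <- wt[i] + wt[i + 1L]
      new_cells <- union(cells[[i]], cells[[i + 1L]])
      mid <- c(mid[seq_len(i - 1L)], new_mid, mid[-seq_len(i + 1L)])
      wt <- c(wt[seq_len(i - 1L)], new_wt, wt[-seq_len(i + 1L)])
      cells <- c(cells[seq_len(i - 1L)], list(new_cells), cells[-seq_len(i + 1L)])
    }
    start <- mid - width %/% 2L
    data.frame(chrom = rep(df$chrom[1], length(mid)),
               start = start, end = start + width,
               cells = I(cells), weight = wt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out
}

#' Collapse per-cell peak files into merged sites and an activity matrix
#'
#' Convenience wrapper: reads one BED per cell type from a manifest,
#' annotates each peak with its source cell, extends to `width`, sorts,
#' merges, and tabulates the binary site-by-cell activity matrix.
#'
#' @param manifest data.frame with columns `cell` and `path`, or the path
#'   of a tab-separated file with those two columns (no header).
#' @param width,overlap_bound,edge_policy passed to [extend_peaks()] and
#'   [merge_peaks()].
#' @return list with `peaks` (merged peak data.frame) and `activity`
#'   (binary matrix, sites x cells).
#' @export
harmonize_peaks <- function(manifest, width = 600L, overlap_bound = 200L,
                            edge_policy = "drop") {
  if (is.character(manifest)) {
    manifest_dir <- dirname(manifest)
    manifest <- utils::read.table(manifest, sep = "\t", header = FALSE,
                                  stringsAsFactors = FALSE,
                                  col.names = c("cell", "path"))
    # paths in a manifest file may be relative to the file's directory
    rel <- !file.exists(manifest$path)
    manifest$path[rel] <- file.path(manifest_dir, manifest$path[rel])
  }
  stopifnot(all(c("cell", "path") %in% names(manifest)))
  all_peaks <- do.call(rbind, lapply(seq_len(nrow(manifest)), function(i) {
    read_bed_peaks(manifest$path[i], cell = manifest$cell[i])
  }))
  ext <- extend_peaks(all_peaks, width = width, edge_policy = edge_policy)
  ext <- ext[order(ext$chrom, ext$start), , drop = FALSE]
  merged <- merge_peaks(ext, width = width, overlap_bound = overlap_bound)
  cells <- sort(unique(manifest$cell))
  activity <- matrix(0L, nrow = nrow(merged), ncol = length(cells),
                     dimnames = list(NULL, cells))
  for (i in seq_len(nrow(merged))) {
    activity[i, match(merged$cells[[i]], cells)] <- 1L
  }
  list(peaks = merged, activity = activity)
}

#' Split site indices into train / validation / test sets
#'
#' Uniform random, seed-reproducible, pairwise disjoint and exhaustive.
#' `test` and `valid` may be fractions (< 1) or absolute counts.
#'
#' @param n_sites total number of sites.
#' @param test,valid fraction or count for the test and validation sets.
#'   Defaults mirror a large-compendium layout: 3.5% test, 3.4%
#'   validation.
#' @param seed integer seed.
#' @return list with integer vectors `train`, `valid`, `test` and the
#'   `seed` used.
#' @export
split_dataset <- function(n_sites, test = 0.035, valid = 0.034, seed = 1L) {
  as_count <- function(x) if (x < 1 && x > 0) round(x * n_sites) else as.integer(x)
  n_test <- as_count(test)
  n_valid <- as_count(valid)
  if (n_test < 0 || n_valid < 0) stop("negative split sizes")
  if (n_test + n_valid > n_sites) {
    stop("requested test (", n_test, ") + validation (", n_valid,
         ") exceed the number of sites (", n_sites, ")")
  }
  idx <- with_seed(seed, sample.int(n_sites))
  test_idx <- sort(idx[seq_len(n_test)])
  valid_idx <- sort(idx[n_test + seq_len(n_valid)])
  train_idx <- sort(idx[-seq_len(n_test + n_valid)])
  if (n_test + n_valid == 0L) train_idx <- sort(idx)
  list(train = train_idx, valid = valid_idx, test = test_idx, seed = seed)
}

#' Assemble an encoded training dataset from merged peaks and a genome
#'
#' Extracts the sequence of every merged site from the genome, one-hot
#' encodes it, and pairs it with the activity matrix. Sites that fall
#' outside their chromosome's bounds are dropped with a warning.
#'
#' @param peaks merged peak data.frame from [merge_peaks()] or
#'   [harmonize_peaks()].
#' @param genome a [Biostrings::DNAStringSet] or path to a FASTA file
#'   containing every chromosome referenced by `peaks`.
#' @param activity binary matrix (sites x cells) aligned to `peaks` rows.
#' @param split optional split from [split_dataset()] computed after any
#'   out-of-bounds drops; if `NULL` a default split is drawn with `seed`.
#' @param seed seed for the default split.
#' @return An `accessnet_dataset`: list with `X` (4 x L x N array), `Y`
#'   (N x T binary matrix), `split`, `cells`, `peaks`.
#' @export
build_dataset <- function(peaks, genome, activity, split = NULL, seed = 1L) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!all(peaks$chrom %in% names(genome))) {
    stop("genome is missing chromosome(s): ",
         paste(setdiff(unique(peaks$chrom), names(genome)), collapse = ", "))
  }
  stopifnot(nrow(activity) == nrow(peaks))
  chrom_len <- Biostrings::width(genome)[match(peaks$chrom, names(genome))]
  ok <- peaks$start >= 0 & peaks$end <= chrom_len
  if (!all(ok)) {
    warning(sum(!ok), " site(s) outside chromosome bounds dropped")
    peaks <- peaks[ok, , drop = FALSE]
    activity <- activity[ok, , drop = FALSE]
  }
  seqs <- as.character(Biostrings::subseq(genome[peaks$chrom],
                                          start = peaks$start + 1L,
                                          end = peaks$end))
  X <- encode_sequences(seqs)
  Y <- activity
  storage.mode(Y) <- "double"
  if (is.null(split)) split <- split_dataset(nrow(Y), seed = seed)
  structure(list(X = X, Y = Y, split = split,
                 cells = colnames(activity), peaks = peaks),
            class = "accessnet_dataset")
}

#' @export
print.accessnet_dataset <- function(x, ...) {
  cat("accessnet_dataset:", dim(x$X)[3], "sites x", ncol(x$Y), "cells,",
      dim(x$X)[2], "bp\n")
  cat("  split: train", length(x$split$train), "/ valid",
      length(x$split$valid), "/ test", length(x$split$test), "\n")
  invisible(x)
}

#' Write merged peaks and the activity table to disk
#'
#' Emits a BED file whose 4th column is the comma-separated active cell
#' set and a TSV activity table (sites x cells).
#'
#' @param harmonized output of [harmonize_peaks()].
#' @param bed_path,activity_path output file paths (either may be `NULL`
#'   to skip).
#' @return invisibly, the paths written.
#' @export
write_harmonized <- function(harmonized, bed_path = NULL, activity_path = NULL) {
  pk <- harmonized$peaks
  if (!is.null(bed_path)) {
    bed <- data.frame(pk$chrom, format(pk$start, scientific = FALSE, trim = TRUE),
                      format(pk$end, scientific = FALSE, trim = TRUE),
                      vapply(pk$cells, paste, "", collapse = ","))
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(activity_path)) {
    act <- data.frame(site = paste0(pk$chrom, ":", pk$start, "-", pk$end),
                      harmonized$activity, check.names = FALSE)
    utils::write.table(act, activity_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(c(bed_path, activity_path))
}

#' Save / load an encoded dataset container
#'
#' Datasets are persisted as a single-file native R container holding the
#' encoded sequence array, the activity matrix, the split indices and the
#' cell labels.
#'
#' @param dataset an `accessnet_dataset`.
#' @param path file path (conventionally `.rds`).
#' @return `save_dataset` returns `path` invisibly; `load_dataset` the
#'   dataset.
#' @export
save_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "accessnet_dataset"))
  saveRDS(dataset, path)
  invisible(path)
}

#' @rdname save_dataset
#' @export
load_dataset <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "accessnet_dataset")) stop("not an accessnet dataset: ", path)
  x
}
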