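#' @title Variant scoring
#'
#' @description
#' Two complementary views of how single-base changes move the model's
#' accessibility predictions. In silico saturation mutagenesis evaluates
#' all 3L single-base mutants of an L-bp sequence for one cell type and
#' summarizes each position by a loss score (reference prediction minus
#' the minimum mutant prediction) and a gain score (maximum mutant
#' prediction minus reference). SNP Accessibility Difference (SAD)
#' profiles score a variant as the vector, over all cell types, of
#' predicted accessibility of the alternative allele minus the reference
#' allele in a window centered on the variant.
#' @name variant_effects
NULL

BASES <- c("A", "C", "G", "T")

#' In silico saturation mutagenesis of one sequence
#'
#' Runs batched forward passes for the reference sequence and all `3L`
#' single-base mutants and records, for the chosen cell, the change in
#' predicted accessibility for every (position, alternative base) pair.
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param seq DNA string or 4 x L one-hot matrix; `L` must equal the
#'   model input length.
#' @param cell target cell index (or name when the model's dataset cells
#'   are attached to `cells`).
#' @param cells optional character vector naming the model targets.
#' @param batch_size forward-pass chunk size.
#' @return a `satmut_result`: list with `delta` (L x 4 matrix, reference
#'   entries 0), `loss` and `gain` (length-L vectors), `ref_prediction`,
#'   `cell`, `seq`.
#' @export
saturation_mutagenesis <- function(model, seq, cell = 1L, cells = NULL,
                                   batch_size = 512L) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  if (is.character(seq)) seq <- one_hot_encode(seq)
  stopifnot(is.matrix(seq), nrow(seq) == 4L)
  L <- ncol(seq)
  if (L != model$spec$input_length) {
    stop("sequence length ", L, " does not match model input length ",
         model$spec$input_length)
  }
  if (is.character(cell)) cell <- match(cell, cells)
  ref_base <- max.col(t(seq))                 # 1..4 (N columns arbitrary)
  muts <- array(seq, dim = c(4L, L, 3L * L))
  pos <- integer(3L * L)
  alt <- integer(3L * L)
  k <- 0L
  for (p in seq_len(L)) {
    for (b in setdiff(1:4, ref_base[p])) {
      k <- k + 1L
      muts[, p, k] <- 0
      muts[ref_base[p], p, k] <- 0
      muts[b, p, k] <- 1
      pos[k] <- p
      alt[k] <- b
    }
  }
  muts <- muts[, , seq_len(k), drop = FALSE]
  ref_pred <- predict(model, seq)[1, cell]
  mut_pred <- predict(model, muts, batch_size = batch_size)[, cell]
  delta <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, BASES))
  delta[cbind(pos, alt)] <- mut_pred - ref_pred
  loss <- ref_pred - vapply(seq_len(L), function(p) {
    min(mut_pred[pos == p])
  }, numeric(1))
  gain <- vapply(seq_len(L), function(p) max(mut_pred[pos == p]),
                 numeric(1)) - ref_pred
  structure(list(delta = delta, loss = loss, gain = gain,
                 ref_prediction = ref_pred, cell = cell,
                 seq = one_hot_decode(seq)),
            class = "satmut_result")
}

#' @export
print.satmut_result <- function(x, ...) {
  cat(sprintf("satmut_result: %d bp, cell %s, ref prediction %.3f\n",
              length(x$loss), x$cell, x$ref_prediction))
  cat(sprintf("  max loss %.3f at %d; max gain %.3f at %d\n",
              max(x$loss), which.max(x$loss), max(x$gain), which.max(x$gain)))
  invisible(x)
}

#' Plot a saturation-mutagenesis heat map
#'
#' Change in predicted accessibility for every (position, alternative
#' base) mutation, with the per-position loss score drawn underneath as
#' reference-base letters whose size is proportional to the loss score
#' beyond a minimum height.
#'
#' @param satmut a `satmut_result`.
#' @param min_height minimum letter size as a fraction of the maximum
#'   (default 0.05).
#' @param range optional integer range of positions to display.
#' @return a ggplot object.
#' @export
plot_satmut <- function(satmut, min_height = 0.05, range = NULL) {
  stopifnot(inherits(satmut, "satmut_result"))
  L <- length(satmut$loss)
  if (is.null(range)) range <- seq_len(L)
  d <- expand.grid(pos = range, base = BASES)
  d$delta <- satmut$delta[cbind(d$pos, match(d$base, BASES))]
  refs <- strsplit(satmut$seq, "")[[1]][range]
  loss <- satmut$loss[range]
  sz <- pmax(loss / max(loss, 1e-9), min_height)
  letters_df <- data.frame(pos = range, base = refs, size = sz)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos, y = .data$base,
                                  fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", name = "Δ pred") +
    ggplot2::geom_text(data = letters_df, inherit.aes = FALSE,
                       ggplot2::aes(x = .data$pos, y = -0.5,
                                    label = .data$base,
                                    size = .data$size),
                       show.legend = FALSE) +
    ggplot2::scale_size_continuous(range = c(1, 4)) +
    ggplot2::labs(x = "position", y = "mutated to") +
    ggplot2::theme_minimal()
}

check_snv <- function(ref, alt) {
  nchar(ref) == 1L && nchar(alt) == 1L &&
    toupper(ref) %in% BASES && toupper(alt) %in% BASES
}

#' SAD profile of a single variant
#'
#' Extracts the model-input window from the genome centered on the
#' variant (the variant sits at 0-based offset `floor(L/2)`), verifies
#' the reference allele, and returns the per-cell difference in predicted
#' accessibility between the alternative and reference alleles.
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param snp list or one-row data.frame with `chrom`, `pos` (1-based, as
#'   in VCF), `id`, `ref`, `alt`.
#' @param window window length; must equal the model input length.
#' @return a `sad_profile`: list with `snp_id`, `ref_allele`,
#'   `alt_allele`, `per_cell_sad` (length-T), `sad_mean`, `ref_pred`,
#'   `alt_pred`.
#' @export
sad_profile <- function(model, genome, snp,
                        window = NULL) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  L <- model$spec$input_length
  window <- window %||% L
  if (window != L) stop("window must equal the model input length ", L)
  ref <- toupper(snp$ref)
  alt <- toupper(snp$alt)
  if (!check_snv(ref, alt)) {
    stop("only single-nucleotide variants are scored (ref '", snp$ref,
         "', alt '", snp$alt, "')")
  }
  pos0 <- as.integer(snp$pos) - 1L          # 0-based variant coordinate
  start0 <- pos0 - L %/% 2L
  chrom <- as.character(snp$chrom)
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  if (start0 < 0 || start0 + L > Biostrings::width(genome[chrom])) {
    stop("window around ", chrom, ":", snp$pos, " falls outside the chromosome")
  }
  win <- toupper(as.character(Biostrings::subseq(genome[[chrom]],
                                                 start = start0 + 1L,
                                                 width = L)))
  offset <- pos0 - start0 + 1L
  genome_base <- substr(win, offset, offset)
  if (genome_base != ref) {
    stop("reference allele mismatch at ", chrom, ":", snp$pos,
         " (genome has ", genome_base, ", VCF says ", ref, ")")
  }
  alt_win <- win
  substr(alt_win, offset, offset) <- alt
  X <- encode_sequences(c(win, alt_win))
  pred <- predict(model, X)
  per_cell <- pred[2, ] - pred[1, ]
  structure(list(snp_id = as.character(snp$id %||% paste0(chrom, ":", snp$pos)),
                 chrom = chrom, pos = as.integer(snp$pos),
                 ref_allele = ref, alt_allele = alt,
                 per_cell_sad = per_cell, sad_mean = mean(per_cell),
                 ref_pred = pred[1, ], alt_pred = pred[2, ]),
            class = "sad_profile")
}

#' SAD profiles for every SNV in a VCF
#'
#' Reads a VCF (plain text or bgzipped), splits multi-allelic records
#' into one profile per alternative allele, skips indels and multi-base
#' alleles with a logged reason, and scores each SNV with
#' [sad_profile()].
#'
#' @param model an `accessnet_model` or `accessnet_fit`.
#' @param vcf_path VCF file.
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param verbose log skipped records.
#' @return a `sad_table` data.frame: `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`, one `sad_<cell>` column per target, `sad_mean`.
#' @export
sad_profiles <- function(model, vcf_path, genome, verbose = TRUE) {
  if (inherits(model, "accessnet_fit")) model <- model$model
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  rows <- list()
  for (i in seq_len(nrow(fix))) {
    ref <- fix[i, "REF"]
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    for (alt in alts) {
      if (!check_snv(ref, alt)) {
        an_message("skipping ", fix[i, "ID"], " (", ref, ">", alt,
                   "): not a single-nucleotide variant", verbose = verbose)
        next
      }
      prof <- sad_profile(model, genome,
                          list(chrom = fix[i, "CHROM"],
                               pos = as.integer(fix[i, "POS"]),
                               id = fix[i, "ID"], ref = ref, alt = alt))
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = prof$snp_id, chrom = prof$chrom, pos = prof$pos,
        ref = prof$ref_allele, alt = prof$alt_allele,
        t(prof$per_cell_sad), sad_mean = prof$sad_mean,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no scoreable SNVs in ", vcf_path)
  out <- do.call(rbind, rows)
  names(out)[6:(5 + model$spec$n_targets)] <-
    paste0("sad_", seq_len(model$spec$n_targets))
  class(out) <- c("sad_table", "data.frame")
  out
}

#' Rank SAD profiles and flag large mean effects
#'
#' Sorts profiles by descending maximum absolute per-cell SAD and flags
#' those whose absolute profile mean exceeds `threshold` (default 0.1, a
#' 10-point change in predicted accessibility probability averaged over
#' cell types).
#'
#' @param profiles a `sad_table` from [sad_profiles()].
#' @param threshold flagging threshold on `|sad_mean|`.
#' @return the table with added `max_abs_sad` and `flagged` columns,
#'   ranked.
#' @export
rank_variants <- function(profiles, threshold = 0.1) {
  stopifnot(nrow(profiles) >= 1L)
  sad_cols <- grep("^sad_[0-9]+$", names(profiles))
  m <- abs(as.matrix(profiles[, sad_cols, drop = FALSE]))
  profiles$max_abs_sad <- apply(m, 1L, max)
  profiles$flagged <- abs(profiles$sad_mean) > threshold
  profiles[order(-profiles$max_abs_sad), , drop = FALSE]
}
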