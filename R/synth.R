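#' @title Synthetic regulatory grammar
#'
#' @description
#' A seeded simulator of a multi-cell accessibility compendium with a
#' known regulatory grammar: background-composition sequences in which
#' sequence motifs are planted under cell-type-specific rules. A site is
#' accessible in a cell exactly when it carries at least one motif
#' cognate to that cell, after which labels are flipped with a small
#' noise probability. Because every plant (motif, position, strand) is
#' recorded, the simulator provides ground truth for every downstream
#' check: learnability, motif recovery, mutagenesis localization and
#' variant discrimination.
#' @name synthetic_data
NULL

# PWM from an IUPAC-ish consensus: the consensus base (or the two bases
# of S/W/R/Y) carries `dominant` probability, the rest is spread evenly.
# The default mimics real TF motifs, whose cores are close to
# deterministic while designated degenerate positions split evenly.
consensus_to_pwm <- function(consensus, dominant = 0.98) {
  two <- list(S = c("C", "G"), W = c("A", "T"), R = c("A", "G"),
              Y = c("C", "T"))
  chars <- strsplit(toupper(consensus), "")[[1]]
  pwm <- matrix(0, nrow = length(chars), ncol = 4L,
                dimnames = list(NULL, c("A", "C", "G", "T")))
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch %in% names(two)) {
      pwm[i, two[[ch]]] <- dominant / 2
      pwm[i, setdiff(c("A", "C", "G", "T"), two[[ch]])] <- (1 - dominant) / 2
    } else {
      pwm[i, ch] <- dominant
      pwm[i, setdiff(c("A", "C", "G", "T"), ch)] <- (1 - dominant) / 3
    }
  }
  pwm
}

#' Default planted-motif set
#'
#' Three motifs echoing well-known accessibility-associated factors: an
#' AP-1-like 7-mer (`TGASTCA`), a CTCF-like 19-mer, and a GC-box-like
#' 8-mer. Cognate cell sets overlap so cells share parts of the grammar:
#' the AP-1-like motif opens cells 1-2, the CTCF-like motif cells 2-3,
#' and the GC-box cells 3-4.
#'
#' @param n_cells number of cells the cognate sets are laid over (>= 4
#'   for the defaults).
#' @return list of motifs, each a list with `id`, `pwm` (W x 4), `cells`
#'   (cognate cell indices), `plant_prob`.
#' @export
default_grammar_motifs <- function(n_cells = 4L) {
  stopifnot(n_cells >= 4L)
  list(
    list(id = "ap1_like", pwm = consensus_to_pwm("TGASTCA"),
         cells = c(1L, 2L), plant_prob = 0.35),
    list(id = "ctcf_like", pwm = consensus_to_pwm("TGGCCACCAGGGGGCGCTA"),
         cells = c(2L, 3L), plant_prob = 0.35),
    list(id = "gc_box", pwm = consensus_to_pwm("GGGGCGGG"),
         cells = c(3L, 4L), plant_prob = 0.35))
}

#' Configure the synthetic grammar
#'
#' @param n_cells number of pseudo cell types.
#' @param n_sites number of sites to simulate.
#' @param seq_length site length in bp.
#' @param background length-4 background nucleotide probabilities
#'   (A,C,G,T); the default is mildly AT-rich like mammalian genomic
#'   background.
#' @param motifs motif list as from [default_grammar_motifs()].
#' @param plant_region 0-based half-open span within the site where plant
#'   starts are drawn (plants must fit inside it); defaults to the central
#'   half of the site.
#' @param label_noise probability of flipping each activity label.
#' @param seed integer seed.
#' @return a `grammar_config` list.
#' @export
grammar_config <- function(n_cells = 4L, n_sites = 10000L, seq_length = 600L,
                           background = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
                           motifs = default_grammar_motifs(n_cells),
                           plant_region = NULL,
                           label_noise = 0.05, seed = 1L) {
  if (is.null(plant_region)) {
    plant_region <- c(floor(seq_length / 4), ceiling(3 * seq_length / 4))
  }
  stopifnot(length(background) == 4L, abs(sum(background) - 1) < 1e-8,
            label_noise >= 0, label_noise < 1,
            plant_region[1] >= 0, plant_region[2] <= seq_length,
            plant_region[2] > plant_region[1])
  for (m in motifs) {
    stopifnot(all(m$cells >= 1L), all(m$cells <= n_cells),
              m$plant_prob >= 0, m$plant_prob <= 1,
              nrow(m$pwm) <= plant_region[2] - plant_region[1])
  }
  structure(list(n_cells = as.integer(n_cells),
                 n_sites = as.integer(n_sites),
                 seq_length = as.integer(seq_length),
                 background = background, motifs = motifs,
                 plant_region = as.integer(plant_region),
                 label_noise = label_noise, seed = as.integer(seed)),
            class = "grammar_config")
}

sample_pwm_instance <- function(pwm) {
  vapply(seq_len(nrow(pwm)), function(i) sample.int(4L, 1L, prob = pwm[i, ]),
         integer(1))
}

pwm_half_max <- function(pwm) 0.5 * prod(apply(pwm, 1L, max))

pwm_score_instance <- function(pwm, inst) {
  prod(pwm[cbind(seq_len(nrow(pwm)), inst)])
}

# A functional (high-affinity) motif instance: a PWM draw conditioned on
# scoring above half of the PWM's maximum score — the same functional
# threshold used for filter interpretation and background cleaning.
sample_functional_instance <- function(pwm, max_tries = 50L) {
  thr <- pwm_half_max(pwm)
  for (i in seq_len(max_tries)) {
    inst <- sample_pwm_instance(pwm)
    if (pwm_score_instance(pwm, inst) > thr) return(inst)
  }
  apply(pwm, 1L, which.max)        # consensus fallback
}

# Rejection-clean background sequence: redraw any window that scores
# above the functional threshold of any grammar motif (either strand)
# until no such window remains. Redraws can themselves create matches,
# so cleaning iterates over the affected sites; a deterministic
# single-base fix handles the (practically unreachable) leftovers.
clean_background <- function(base_int, config, max_rounds = 30L) {
  L <- nrow(base_int)
  n <- ncol(base_int)
  X <- array(0, dim = c(4L, L, n))
  X[cbind(as.vector(base_int), rep(seq_len(L), times = n),
          rep(seq_len(n), each = L))] <- 1
  set_window <- function(site, span, newb) {
    base_int[span, site] <<- newb
    X[, span, site] <<- 0
    X[cbind(newb, span, rep.int(site, length(span)))] <<- 1
  }
  dirty <- seq_len(n)
  for (round in seq_len(max_rounds)) {
    touched <- integer(0)
    for (m in config$motifs) {
      hits <- scan_functional_hits(X, m$pwm, sites = dirty)
      W <- nrow(m$pwm)
      for (h in seq_len(nrow(hits))) {
        span <- hits$pos[h]:(hits$pos[h] + W - 1L)
        set_window(hits$site[h], span,
                   sample.int(4L, W, replace = TRUE,
                              prob = config$background))
        touched <- c(touched, hits$site[h])
      }
    }
    if (length(touched) == 0L) return(base_int)
    dirty <- unique(touched)
  }
  for (m in config$motifs) {            # deterministic removal
    hits <- scan_functional_hits(X, m$pwm, sites = dirty)
    for (h in seq_len(nrow(hits))) {
      pwm <- if (hits$strand[h] == 1L) m$pwm else
        reverse_complement_pwm(m$pwm)
      j <- which.max(apply(pwm, 1L, max))
      set_window(hits$site[h], hits$pos[h] + j - 1L,
                 which.min(pwm[j, ]))
    }
  }
  base_int
}

# Scan one-hot sites for windows whose PWM score exceeds the functional
# threshold, on either strand. Returns a data.frame (site, pos, strand
# index) of hits; scoring is a log-probability convolution.
scan_functional_hits <- function(X, pwm, sites = seq_len(dim(X)[3]),
                                 chunk = 200L) {
  W <- nrow(pwm)
  L <- dim(X)[2]
  P <- L - W + 1L
  filt <- rbind(as.vector(t(log(pwm))),
                as.vector(t(log(reverse_complement_pwm(pwm)))))
  thr <- log(pwm_half_max(pwm))
  hits <- list()
  for (s in seq(1L, length(sites), by = chunk)) {
    take <- sites[s:min(s + chunk - 1L, length(sites))]
    Z <- filt %*% cpp_im2col(X[, , take, drop = FALSE], 4L, L,
                             length(take), W)
    idx <- which(Z > thr, arr.ind = TRUE)
    if (nrow(idx)) {
      col <- idx[, 2]
      hits[[length(hits) + 1L]] <- data.frame(
        site = take[(col - 1L) %/% P + 1L],
        pos = (col - 1L) %% P + 1L,
        strand = idx[, 1])
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(site = integer(), pos = integer(), strand = integer())
}

#' Generate a synthetic peak compendium with known grammar
#'
#' Samples background bases i.i.d. from the configured composition and
#' rejection-cleans the background of functional motif matches: any
#' window scoring above half of a grammar PWM's maximum score (on either
#' strand) is redrawn, so that motif presence is a deterministic
#' property of the sequence. Each motif then plants independently with
#' its plant probability at a uniform position in the plant region;
#' planted instances are drawn from the motif PWM conditioned on scoring
#' above the same functional threshold (high-affinity sites), strand
#' uniform with the PWM reverse-complemented on the minus strand. A site
#' is active in a cell exactly when it carries a cognate plant; labels
#' are finally flipped with the configured noise. Overlapping plants are
#' re-drawn (up to 10 positions) and skipped if no free position is
#' found. Everything is reproducible from `config$seed`.
#'
#' @param config a [grammar_config()].
#' @return an `accessnet_synth`: list with `seqs` (character vector), `X`
#'   (4 x L x N one-hot array), `Y` (noisy N x T activity matrix),
#'   `Y_clean` (pre-noise labels), `truth` (data.frame: site, motif,
#'   start (0-based within site), strand), `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "grammar_config"))
  n <- config$n_sites
  L <- config$seq_length
  Tn <- config$n_cells
  with_seed(config$seed, {
    base_int <- matrix(sample.int(4L, n * L, replace = TRUE,
                                  prob = config$background),
                       nrow = L, ncol = n)
    base_int <- clean_background(base_int, config)
    truth <- list()
    planted <- matrix(FALSE, nrow = n, ncol = length(config$motifs))
    lo <- config$plant_region[1]
    hi <- config$plant_region[2]
    plant_flags <- matrix(stats::runif(n * length(config$motifs)) <
                            vapply(config$motifs, `[[`, 0, "plant_prob")[
                              rep(seq_along(config$motifs), each = n)],
                          nrow = n)
    for (i in seq_len(n)) {
      occupied <- integer(0)
      for (mi in seq_along(config$motifs)) {
        if (!plant_flags[i, mi]) next
        m <- config$motifs[[mi]]
        W <- nrow(m$pwm)
        ok <- FALSE
        for (try in seq_len(10L)) {
          start0 <- lo + sample.int(hi - lo - W + 1L, 1L) - 1L
          span <- (start0 + 1L):(start0 + W)
          if (!any(span %in% occupied)) { ok <- TRUE; break }
        }
        if (!ok) next   # crowded site: plant skipped
        strand <- sample(c("+", "-"), 1L)
        pwm <- if (strand == "+") m$pwm else reverse_complement_pwm(m$pwm)
        base_int[span, i] <- sample_functional_instance(pwm)
        occupied <- c(occupied, span)
        planted[i, mi] <- TRUE
        truth[[length(truth) + 1L]] <- data.frame(
          site = i, motif = m$id, start = start0, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
    Y_clean <- matrix(0, nrow = n, ncol = Tn,
                      dimnames = list(NULL, paste0("cell", seq_len(Tn))))
    for (mi in seq_along(config$motifs)) {
      for (cc in config$motifs[[mi]]$cells) {
        Y_clean[planted[, mi], cc] <- 1
      }
    }
    flips <- matrix(stats::runif(n * Tn) < config$label_noise, nrow = n)
    Y <- abs(Y_clean - flips)
    X <- array(0, dim = c(4L, L, n),
               dimnames = list(c("A", "C", "G", "T"), NULL, NULL))
    X[cbind(as.vector(base_int),
            rep(seq_len(L), times = n),
            rep(seq_len(n), each = L))] <- 1
    seqs <- apply(matrix(c("A", "C", "G", "T")[base_int], nrow = L), 2L,
                  paste, collapse = "")
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(site = integer(), motif = character(), start = integer(),
                 strand = character())
    structure(list(seqs = seqs, X = X, Y = Y, Y_clean = Y_clean,
                   truth = truth, config = config),
              class = "accessnet_synth")
  })
}

#' @export
print.accessnet_synth <- function(x, ...) {
  cat("accessnet_synth:", x$config$n_sites, "sites x", x$config$n_cells,
      "cells,", x$config$seq_length, "bp;", nrow(x$truth), "plants\n")
  invisible(x)
}

#' Wrap a synthetic compendium as an encoded training dataset
#'
#' @param synth an `accessnet_synth`.
#' @param test,valid,seed passed to [split_dataset()].
#' @return an `accessnet_dataset`.
#' @export
synth_to_dataset <- function(synth, test = 0.035, valid = 0.034, seed = 1L) {
  stopifnot(inherits(synth, "accessnet_synth"))
  split <- split_dataset(synth$config$n_sites, test = test, valid = valid,
                         seed = seed)
  structure(list(X = synth$X, Y = synth$Y, split = split,
                 cells = colnames(synth$Y), peaks = NULL,
                 truth = synth$truth),
            class = "accessnet_dataset")
}

#' Genomic layout of a synthetic compendium
#'
#' Sites are concatenated onto a single synthetic chromosome (`chrS`)
#' separated by background spacers, so the compendium can be written as a
#' genome FASTA plus a site BED and exercised through the same file paths
#' as real data.
#'
#' @param config a `grammar_config` (or `accessnet_synth`).
#' @param spacer bp of background sequence between consecutive sites (and
#'   at both ends).
#' @return data.frame with `site`, `chrom`, `start`, `end` (0-based
#'   half-open genome coordinates), plus the total `chrom_length` as an
#'   attribute.
#' @export
synth_layout <- function(config, spacer = 400L) {
  if (inherits(config, "accessnet_synth")) config <- config$config
  n <- config$n_sites
  L <- config$seq_length
  start <- spacer + (seq_len(n) - 1L) * (L + spacer)
  out <- data.frame(site = seq_len(n), chrom = "chrS", start = start,
                    end = start + L)
  attr(out, "chrom_length") <- spacer + n * (L + spacer)
  out
}

#' Write a synthetic compendium to disk
#'
#' Emits the concatenated genome FASTA (spacers are drawn from the
#' background composition with a seed derived from the grammar seed), a
#' BED of site coordinates, the activity table (TSV), per-cell peak BED
#' files with a manifest, and the ground truth + configuration echo as
#' JSON.
#'
#' @param synth an `accessnet_synth`.
#' @param dir output directory (created if needed).
#' @param spacer spacer width, see [synth_layout()].
#' @return invisibly, a list with the written `paths`, the `layout` and
#'   the per-cell `manifest` data.frame.
#' @export
write_synth <- function(synth, dir, spacer = 400L) {
  stopifnot(inherits(synth, "accessnet_synth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- synth$config
  layout <- synth_layout(cfg, spacer = spacer)
  n <- cfg$n_sites
  total <- attr(layout, "chrom_length")
  genome_chars <- with_seed(derive_seed(cfg$seed, 99), {
    g <- sample(c("A", "C", "G", "T"), total, replace = TRUE,
                prob = cfg$background)
    g
  })
  for (i in seq_len(n)) {
    g_span <- (layout$start[i] + 1L):layout$end[i]
    genome_chars[g_span] <- strsplit(synth$seqs[i], "")[[1]]
  }
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chrS"
  paths <- list(fasta = file.path(dir, "genome.fa"),
                bed = file.path(dir, "sites.bed"),
                activity = file.path(dir, "activity.tsv"),
                truth = file.path(dir, "truth.json"),
                manifest = file.path(dir, "manifest.tsv"))
  Biostrings::writeXStringSet(genome, paths$fasta, width = 70L)
  utils::write.table(
    data.frame(layout$chrom, layout$start, layout$end,
               paste0("site_", layout$site)),
    paths$bed, sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = FALSE)
  utils::write.table(
    data.frame(site = paste0("site_", layout$site), synth$Y,
               check.names = FALSE),
    paths$activity, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- write_cell_beds(synth, dir, layout)
  utils::write.table(manifest, paths$manifest, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(config = list(n_cells = cfg$n_cells, n_sites = cfg$n_sites,
                       seq_length = cfg$seq_length,
                       background = unname(cfg$background),
                       label_noise = cfg$label_noise, seed = cfg$seed,
                       plant_region = cfg$plant_region,
                       motifs = lapply(cfg$motifs, function(m) {
                         list(id = m$id, cells = m$cells,
                              plant_prob = m$plant_prob,
                              consensus = pwm_consensus(m$pwm))
                       })),
         layout = layout, truth = synth$truth),
    paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, layout = layout, manifest = manifest))
}

# Per-cell peak BED files emulating raw peak calls: each active site
# yields one peak of random width (150-400 bp) whose midpoint jitters
# around the site center, so the harmonization step has real work to do.
write_cell_beds <- function(synth, dir, layout, jitter = 50L) {
  cfg <- synth$config
  with_seed(derive_seed(cfg$seed, 7), {
    center <- (layout$start + layout$end) %/% 2L
    files <- character(cfg$n_cells)
    for (cc in seq_len(cfg$n_cells)) {
      act <- which(synth$Y[, cc] == 1)
      w <- sample(150:400, length(act), replace = TRUE)
      mid <- center[act] + sample(-jitter:jitter, length(act), replace = TRUE)
      start <- pmax(0L, mid - w %/% 2L)
      files[cc] <- file.path(dir, sprintf("peaks_cell%d.bed", cc))
      utils::write.table(data.frame("chrS", start, start + w),
                         files[cc], sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
    # manifest paths are relative to the output directory, so the written
    # compendium is portable (and byte-identical across runs)
    data.frame(cell = paste0("cell", seq_len(cfg$n_cells)),
               path = basename(files), stringsAsFactors = FALSE)
  })
}

#' Generate labeled causal and bystander variants for a synthetic genome
#'
#' Causal SNPs substitute the most informative position of a planted
#' motif instance with the motif's least probable base there, destroying
#' the match; bystander SNPs hit background positions at least 10 bp away
#' from every plant footprint. Coordinates refer to the concatenated
#' synthetic genome of [synth_layout()].
#'
#' @param synth an `accessnet_synth` with at least one plant.
#' @param n_causal,n_bystander number of variants of each class.
#' @param seed integer seed.
#' @param spacer spacer width used for the genome layout.
#' @return a data.frame with `chrom`, `pos` (1-based), `id`, `ref`,
#'   `alt`, `causal`, `site`, `motif`.
#' @export
generate_variant_set <- function(synth, n_causal = 100L, n_bystander = 100L,
                                 seed = 1L, spacer = 400L) {
  stopifnot(inherits(synth, "accessnet_synth"))
  truth <- synth$truth
  if (nrow(truth) < n_causal) {
    stop("not enough planted motifs (", nrow(truth), ") for ", n_causal,
         " causal variants")
  }
  cfg <- synth$config
  layout <- synth_layout(cfg, spacer = spacer)
  motif_by_id <- stats::setNames(cfg$motifs,
                                 vapply(cfg$motifs, `[[`, "", "id"))
  with_seed(seed, {
    rows <- list()
    picks <- sample.int(nrow(truth), n_causal)
    for (k in picks) {
      m <- motif_by_id[[truth$motif[k]]]
      pwm <- if (truth$strand[k] == "+") m$pwm else
        reverse_complement_pwm(m$pwm)
      j <- which.max(apply(pwm, 1L, max))       # most informative position
      site <- truth$site[k]
      site_pos0 <- truth$start[k] + j - 1L
      ref <- substr(synth$seqs[site], site_pos0 + 1L, site_pos0 + 1L)
      worst <- c("A", "C", "G", "T")[order(pwm[j, ])]
      alt <- if (worst[1] == ref) worst[2] else worst[1]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chrS", pos = layout$start[site] + site_pos0 + 1L,
        id = sprintf("causal_%d", length(rows) + 1L),
        ref = ref, alt = alt, causal = TRUE, site = site,
        motif = m$id, stringsAsFactors = FALSE)
    }
    footprints <- split(truth, truth$site)
    sites <- sample(cfg$n_sites, n_bystander * 3L, replace = TRUE)
    made <- 0L
    for (site in sites) {
      if (made >= n_bystander) break
      fp <- footprints[[as.character(site)]]
      blocked <- integer(0)
      if (!is.null(fp)) {
        for (r in seq_len(nrow(fp))) {
          W <- nrow(motif_by_id[[fp$motif[r]]]$pwm)
          blocked <- c(blocked, (fp$start[r] - 10L):(fp$start[r] + W - 1L + 10L))
        }
      }
      free <- setdiff(seq_len(cfg$seq_length) - 1L, blocked)
      if (length(free) == 0L) next
      site_pos0 <- sample(free, 1L)
      ref <- substr(synth$seqs[site], site_pos0 + 1L, site_pos0 + 1L)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
      made <- made + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = "chrS", pos = layout$start[site] + site_pos0 + 1L,
        id = sprintf("bystander_%d", made), ref = ref, alt = alt,
        causal = FALSE, site = site, motif = NA_character_,
        stringsAsFactors = FALSE)
    }
    if (made < n_bystander) stop("could not place ", n_bystander,
                                 " bystander variants")
    do.call(rbind, rows)
  })
}

#' Write a variant set as a minimal VCF (plus a truth label TSV)
#'
#' @param variants data.frame from [generate_variant_set()].
#' @param path output VCF path.
#' @param chrom_length contig length for the VCF header (from
#'   [synth_layout()]).
#' @param labels_path optional TSV path for the causal/bystander truth
#'   labels.
#' @return invisibly, `path`.
#' @export
write_variant_vcf <- function(variants, path, chrom_length,
                              labels_path = NULL) {
  v <- variants[order(variants$pos), , drop = FALSE]
  con <- file(path, "w")
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=chrS,length=%d>", chrom_length),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  writeLines(sprintf("%s\t%d\t%s\t%s\t%s\t.\tPASS\t.", v$chrom, v$pos,
                     v$id, v$ref, v$alt), con)
  close(con)
  if (!is.null(labels_path)) {
    utils::write.table(variants[, c("id", "causal", "site", "motif")],
                       labels_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
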