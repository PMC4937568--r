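small_variant_world <- function(seed = 51) {
  spec <- architecture_spec(40, 3, conv_layers = list(c(4, 7, 3)),
                            fc_layers = 6, dropout = 0)
  model <- random_eval_model(spec, seed = seed)
  set.seed(seed + 1)
  chrom <- random_dna(400)
  genome <- Biostrings::DNAStringSet(c(chrS = chrom))
  list(model = model, genome = genome, chrom = chrom)
}

test_that("saturation mutagenesis of a constant model is identically zero", {
  w <- small_variant_world()
  m <- w$model
  m$params$out$W[] <- 0
  m$params$out$b[] <- 0
  sm <- saturation_mutagenesis(m, substr(w$chrom, 1, 40), cell = 2)
  expect_equal(sm$ref_prediction, 0.5)
  expect_equal(sm$delta, matrix(0, 40, 4), ignore_attr = TRUE)
  expect_equal(sm$loss, rep(0, 40))
  expect_equal(sm$gain, rep(0, 40))
})

test_that("mutation deltas are exact per-mutant differences with zero reference entries", {
  w <- small_variant_world()
  s <- substr(w$chrom, 11, 50)
  sm <- saturation_mutagenesis(w$model, s, cell = 1)
  ref <- strsplit(s, "")[[1]]
  bases <- c("A", "C", "G", "T")
  # reference entries are zero; spot-check mutants against direct forwards
  for (p in c(1, 7, 23, 40)) {
    expect_equal(unname(sm$delta[p, ref[p]]), 0)
    for (b in setdiff(bases, ref[p])) {
      mut <- ref
      mut[p] <- b
      pm <- predict(w$model, one_hot_encode(paste(mut, collapse = "")))[1, 1]
      expect_equal(unname(sm$delta[p, b]), pm - sm$ref_prediction,
                   tolerance = 1e-12)
    }
  }
  # loss/gain are the extreme differences over the three mutants only
  for (p in seq_len(40)) {
    mut_deltas <- sm$delta[p, setdiff(bases, ref[p])]
    expect_equal(sm$gain[p], max(mut_deltas))
    expect_equal(sm$loss[p], -min(mut_deltas))
    expect_gte(sm$gain[p] + sm$loss[p], 0)
  }
})

test_that("gain plus loss is non-negative at every position", {
  w <- small_variant_world(seed = 52)
  sm <- saturation_mutagenesis(w$model, substr(w$chrom, 1, 40), cell = 3)
  expect_true(all(sm$gain + sm$loss >= -1e-12))
})

test_that("sequence length must match the model input", {
  w <- small_variant_world()
  expect_error(saturation_mutagenesis(w$model, substr(w$chrom, 1, 30)),
               "input length")
})

test_that("SAD profiles score alleles in a variant-centered window", {
  w <- small_variant_world()
  pos <- 201
  ref <- substr(w$chrom, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  prof <- sad_profile(w$model, w$genome,
                      list(chrom = "chrS", pos = pos, id = "v1",
                           ref = ref, alt = alt))
  expect_length(prof$per_cell_sad, 3)
  expect_equal(prof$sad_mean, mean(prof$per_cell_sad))
  expect_true(all(abs(prof$per_cell_sad) < 1))
  # matches a direct two-window computation
  win <- substr(w$chrom, pos - 20, pos + 19)
  alt_win <- win
  substr(alt_win, 21, 21) <- alt
  pr <- predict(w$model, encode_sequences(c(win, alt_win)))
  expect_equal(prof$per_cell_sad, pr[2, ] - pr[1, ], tolerance = 1e-12)
  # alt equal to ref is a predicted no-op
  prof0 <- sad_profile(w$model, w$genome,
                       list(chrom = "chrS", pos = pos, id = "v0",
                            ref = ref, alt = ref))
  expect_equal(prof0$per_cell_sad, rep(0, 3))
})

test_that("SAD is exactly antisymmetric under allele swap", {
  w <- small_variant_world(seed = 53)
  pos <- 120
  ref <- substr(w$chrom, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[2]
  fwd <- sad_profile(w$model, w$genome,
                     list(chrom = "chrS", pos = pos, id = "x", ref = ref,
                          alt = alt))
  swapped <- w$chrom
  substr(swapped, pos, pos) <- alt
  genome2 <- Biostrings::DNAStringSet(c(chrS = swapped))
  rev <- sad_profile(w$model, genome2,
                     list(chrom = "chrS", pos = pos, id = "x", ref = alt,
                          alt = ref))
  expect_equal(rev$per_cell_sad, -fwd$per_cell_sad, tolerance = 0)
})

test_that("saturation mutagenesis and SAD agree at the variant position", {
  w <- small_variant_world(seed = 54)
  pos <- 101                      # window is [81, 121)
  win <- substr(w$chrom, pos - 20, pos + 19)
  sm <- saturation_mutagenesis(w$model, win, cell = 2)
  ref <- substr(w$chrom, pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  prof <- sad_profile(w$model, w$genome,
                      list(chrom = "chrS", pos = pos, id = "y", ref = ref,
                           alt = alt))
  expect_equal(prof$per_cell_sad[2], unname(sm$delta[21, alt]),
               tolerance = 1e-12)
})

test_that("SAD rejects bad alleles and mismatched references", {
  w <- small_variant_world()
  expect_error(sad_profile(w$model, w$genome,
                           list(chrom = "chrS", pos = 100, id = "i",
                                ref = "AT", alt = "A")),
               "single-nucleotide")
  ref <- substr(w$chrom, 100, 100)
  wrong <- setdiff(c("A", "C", "G", "T"), ref)[1]
  expect_error(sad_profile(w$model, w$genome,
                           list(chrom = "chrS", pos = 100, id = "m",
                                ref = wrong, alt = ref)),
               "mismatch")
  expect_error(sad_profile(w$model, w$genome,
                           list(chrom = "chrS", pos = 5, id = "e",
                                ref = "A", alt = "C")),
               "outside")
})

test_that("VCF scoring splits multi-allelic records and skips indels", {
  w <- small_variant_world(seed = 55)
  pos <- c(150, 250)
  refs <- vapply(pos, function(p) substr(w$chrom, p, p), "")
  alts1 <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[1], "")
  alts2 <- vapply(refs, function(r) setdiff(c("A", "C", "G", "T"), r)[2], "")
  dir <- withr::local_tempdir()
  vcf <- file.path(dir, "test.vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##contig=<ID=chrS,length=400>",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("chrS\t%d\tsnp1\t%s\t%s,%s\t.\tPASS\t.",
                       pos[1], refs[1], alts1[1], alts2[1]),
               sprintf("chrS\t%d\tindel1\t%s\t%sA\t.\tPASS\t.",
                       pos[1], refs[1], refs[1]),
               sprintf("chrS\t%d\tsnp2\t%s\t%s\t.\tPASS\t.",
                       pos[2], refs[2], alts1[2])), vcf)
  tab <- suppressMessages(sad_profiles(w$model, vcf, w$genome,
                                       verbose = FALSE))
  expect_equal(nrow(tab), 3L)            # two alleles of snp1 + snp2
  expect_setequal(tab$snp_id, c("snp1", "snp1", "snp2"))
  expect_named(tab, c("snp_id", "chrom", "pos", "ref", "alt",
                      paste0("sad_", 1:3), "sad_mean"))
  ranked <- rank_variants(tab, threshold = 0.001)
  expect_equal(ranked$max_abs_sad, sort(ranked$max_abs_sad,
                                        decreasing = TRUE))
  expect_type(ranked$flagged, "logical")
})

test_that("rank_variants flags exactly the profiles above the mean threshold", {
  tab <- data.frame(snp_id = c("a", "b", "c"), chrom = "chrS",
                    pos = 1:3, ref = "A", alt = "C",
                    sad_1 = c(0, 0.25, 0.02), sad_2 = c(0, 0.15, -0.02),
                    sad_mean = c(0, 0.2, 0))
  class(tab) <- c("sad_table", "data.frame")
  ranked <- rank_variants(tab, threshold = 0.1)
  expect_equal(sum(ranked$flagged), 1L)
  expect_equal(ranked$snp_id[1], "b")
  # all-zero profiles: nothing flagged
  tab0 <- tab
  tab0[, c("sad_1", "sad_2", "sad_mean")] <- 0
  expect_equal(sum(rank_variants(tab0, 0.1)$flagged), 0L)
})

test_that("the mutagenesis heat map renders", {
  w <- small_variant_world()
  sm <- saturation_mutagenesis(w$model, substr(w$chrom, 1, 40), cell = 1)
  p <- plot_satmut(sm, range = 1:20)
  expect_s3_class(p, "ggplot")
})
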