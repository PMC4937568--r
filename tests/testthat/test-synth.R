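small_grammar <- function(n_sites = 200, noise = 0, seed = 61,
                          plant_prob = 0.5) {
  motifs <- default_grammar_motifs()
  for (i in seq_along(motifs)) motifs[[i]]$plant_prob <- plant_prob
  grammar_config(n_sites = n_sites, seq_length = 200,
                 plant_region = c(50L, 150L), motifs = motifs,
                 label_noise = noise, seed = seed)
}

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_dataset(small_grammar())
  b <- generate_dataset(small_grammar())
  expect_identical(a$seqs, b$seqs)
  expect_identical(a$Y, b$Y)
  expect_identical(a$truth, b$truth)
  d <- generate_dataset(small_grammar(seed = 62))
  expect_false(identical(a$seqs, d$seqs))
})

test_that("noiseless activity equals the cognate-motif indicator exactly", {
  synth <- generate_dataset(small_grammar())
  cfg <- synth$config
  has_motif <- function(id) {
    sites <- unique(synth$truth$site[synth$truth$motif == id])
    as.numeric(seq_len(cfg$n_sites) %in% sites)
  }
  for (m in cfg$motifs) {
    ind <- has_motif(m$id)
    for (cc in m$cells) {
      # every site with a cognate plant is active in that cell
      expect_true(all(synth$Y[ind == 1, cc] == 1))
    }
  }
  # cell 1's only cognate motif is the AP-1-like one
  expect_equal(unname(synth$Y[, 1]), has_motif("ap1_like"))
  expect_identical(synth$Y, synth$Y_clean)
})

test_that("zero plant probability yields silent sites; label noise flips labels", {
  s0 <- generate_dataset(small_grammar(plant_prob = 0))
  expect_equal(sum(s0$Y), 0)
  expect_equal(nrow(s0$truth), 0L)
  sn <- generate_dataset(small_grammar(n_sites = 2000, noise = 0.05))
  flip_rate <- mean(sn$Y != sn$Y_clean)
  expect_gt(flip_rate, 0.05 - 3 * sqrt(0.05 * 0.95 / (2000 * 4)))
  expect_lt(flip_rate, 0.05 + 3 * sqrt(0.05 * 0.95 / (2000 * 4)))
})

test_that("plant fraction and base composition obey binomial bounds", {
  cfg <- grammar_config(n_sites = 3000, seq_length = 200,
                        plant_region = c(50L, 150L), label_noise = 0,
                        seed = 63)
  synth <- generate_dataset(cfg)
  for (m in cfg$motifs) {
    frac <- length(unique(synth$truth$site[synth$truth$motif == m$id])) /
      cfg$n_sites
    sd3 <- 3 * sqrt(0.35 * 0.65 / cfg$n_sites)
    expect_gt(frac, 0.35 - sd3 - 0.01)  # small allowance for skipped plants
    expect_lt(frac, 0.35 + sd3)
  }
  # background composition: count bases outside plant footprints
  bg_sites <- setdiff(seq_len(cfg$n_sites), unique(synth$truth$site))
  counts <- table(factor(unlist(strsplit(synth$seqs[bg_sites[1:200]], "")),
                         levels = c("A", "C", "G", "T")))
  n <- sum(counts)
  for (b in c("A", "C", "G", "T")) {
    p <- cfg$background[b]
    expect_lt(abs(counts[[b]] / n - p), 3 * sqrt(p * (1 - p) / n))
  }
})

test_that("plants sit inside the plant region and never overlap", {
  synth <- generate_dataset(small_grammar(n_sites = 400))
  cfg <- synth$config
  widths <- vapply(cfg$motifs, function(m) nrow(m$pwm), 1L)
  names(widths) <- vapply(cfg$motifs, `[[`, "", "id")
  expect_true(all(synth$truth$start >= cfg$plant_region[1]))
  expect_true(all(synth$truth$start + widths[synth$truth$motif] <=
                    cfg$plant_region[2]))
  for (s in split(synth$truth, synth$truth$site)) {
    if (nrow(s) < 2) next
    o <- order(s$start)
    ends <- s$start[o] + widths[s$motif[o]]
    expect_true(all(s$start[o][-1] >= ends[-nrow(s)]))
  }
  # planted instances decode to near-consensus sequences on the right strand
  row <- synth$truth[synth$truth$motif == "ap1_like", ][1, ]
  inst <- substr(synth$seqs[row$site], row$start + 1, row$start + 7)
  pwm <- cfg$motifs[[1]]$pwm
  if (row$strand == "-") pwm <- reverse_complement_pwm(pwm)
  sc <- prod(pwm[cbind(1:7, match(strsplit(inst, "")[[1]],
                                  c("A", "C", "G", "T")))])
  expect_gt(sc, 0)
})

test_that("ground-truth labels give a perfect classifier at zero noise", {
  synth <- generate_dataset(small_grammar(n_sites = 300))
  cfg <- synth$config
  for (cc in seq_len(cfg$n_cells)) {
    cognate <- vapply(cfg$motifs,
                      function(m) cc %in% m$cells, TRUE)
    ids <- vapply(cfg$motifs, `[[`, "", "id")[cognate]
    score <- as.numeric(seq_len(cfg$n_sites) %in%
                          synth$truth$site[synth$truth$motif %in% ids])
    if (length(unique(synth$Y[, cc])) < 2) next
    expect_equal(auc_score(synth$Y[, cc], score), 1)
  }
})

test_that("written compendium files round-trip coherently", {
  synth <- generate_dataset(small_grammar(n_sites = 40))
  dir <- withr::local_tempdir()
  res <- write_synth(synth, dir, spacer = 250)
  for (p in res$paths) expect_true(file.exists(p))
  genome <- Biostrings::readDNAStringSet(res$paths$fasta)
  expect_equal(unname(Biostrings::width(genome)),
               attr(res$layout, "chrom_length"))
  # site sequences are embedded at their BED coordinates
  for (i in c(1, 17, 40)) {
    slice <- as.character(Biostrings::subseq(genome[[1]],
                                             res$layout$start[i] + 1,
                                             res$layout$end[i]))
    expect_identical(slice, synth$seqs[i])
  }
  # harmonizing the emitted per-cell BEDs reproduces sites near the truth
  hz <- harmonize_peaks(res$paths$manifest, width = 200,
                        overlap_bound = 70)
  expect_gt(nrow(hz$peaks), 0)
  expect_identical(colnames(hz$activity), paste0("cell", 1:4))
  # activity table matches the in-memory labels
  act <- read.delim(res$paths$activity)
  expect_equal(unname(as.matrix(act[, -1])), unname(synth$Y))
  truth <- jsonlite::read_json(res$paths$truth, simplifyVector = TRUE)
  expect_equal(truth$config$seed, synth$config$seed)
  expect_equal(nrow(truth$truth), nrow(synth$truth))
})

test_that("causal variants break their motif match; bystanders avoid plants", {
  synth <- generate_dataset(small_grammar(n_sites = 300))
  cfg <- synth$config
  vars <- generate_variant_set(synth, n_causal = 30, n_bystander = 30,
                               seed = 64, spacer = 250)
  expect_equal(sum(vars$causal), 30L)
  expect_equal(sum(!vars$causal), 30L)
  layout <- synth_layout(cfg, spacer = 250)
  widths <- setNames(vapply(cfg$motifs, function(m) nrow(m$pwm), 1L),
                     vapply(cfg$motifs, `[[`, "", "id"))
  motif_by_id <- setNames(cfg$motifs, names(widths))
  for (i in which(vars$causal)) {
    v <- vars[i, ]
    site_pos0 <- v$pos - 1 - layout$start[v$site]
    # the variant hits inside a plant footprint of its motif
    tr <- synth$truth[synth$truth$site == v$site &
                        synth$truth$motif == v$motif, ]
    hit <- any(site_pos0 >= tr$start & site_pos0 < tr$start + widths[v$motif])
    expect_true(hit)
    # the VCF ref matches the sequence, and the substitution drops the
    # PWM match score below half of the PWM's own maximum
    inst_row <- tr[site_pos0 >= tr$start &
                     site_pos0 < tr$start + widths[v$motif], ][1, ]
    pwm <- motif_by_id[[v$motif]]$pwm
    if (inst_row$strand == "-") pwm <- reverse_complement_pwm(pwm)
    inst <- substr(synth$seqs[v$site], inst_row$start + 1,
                   inst_row$start + widths[v$motif])
    expect_identical(substr(synth$seqs[v$site], site_pos0 + 1, site_pos0 + 1),
                     v$ref)
    mut <- inst
    substr(mut, site_pos0 - inst_row$start + 1,
           site_pos0 - inst_row$start + 1) <- v$alt
    score <- function(s) prod(pwm[cbind(seq_len(nchar(s)),
                                        match(strsplit(s, "")[[1]],
                                              c("A", "C", "G", "T")))])
    expect_lt(score(mut), 0.5 * prod(apply(pwm, 1, max)))
  }
  for (i in which(!vars$causal)) {
    v <- vars[i, ]
    site_pos0 <- v$pos - 1 - layout$start[v$site]
    tr <- synth$truth[synth$truth$site == v$site, ]
    if (nrow(tr) == 0) next
    gaps <- abs(site_pos0 - (tr$start + widths[tr$motif] / 2))
    expect_true(all(site_pos0 < tr$start - 10 |
                      site_pos0 >= tr$start + widths[tr$motif] + 10))
  }
  # regeneration is bit-identical
  expect_identical(vars, generate_variant_set(synth, 30, 30, seed = 64,
                                              spacer = 250))
})

test_that("the variant VCF is readable by standard VCF tooling", {
  synth <- generate_dataset(small_grammar(n_sites = 100))
  vars <- generate_variant_set(synth, 10, 10, seed = 65, spacer = 250)
  dir <- withr::local_tempdir()
  vcf_path <- file.path(dir, "v.vcf")
  lab_path <- file.path(dir, "lab.tsv")
  write_variant_vcf(vars, vcf_path,
                    attr(synth_layout(synth, 250), "chrom_length"),
                    labels_path = lab_path)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  expect_equal(nrow(v@fix), 20L)
  expect_true(all(vcfR::getFIX(v)[, "REF"] %in% c("A", "C", "G", "T")))
  labs <- read.delim(lab_path)
  expect_equal(sum(labs$causal), 10L)
})
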