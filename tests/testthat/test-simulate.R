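small_cfg <- function(seed = 5L, n_reads = 3000L, ...) {
  sim_config(seed = seed, n_chroms = 2L, chrom_length = 60000L,
             n_coding_genes = 20L, n_reads = n_reads, ...)
}

test_that("genome and annotation are byte-identical under a fixed seed", {
  dir <- withr::local_tempdir()
  for (run in 1:2) {
    sim <- simulate_genome(small_cfg())
    write_sim_fasta(sim, file.path(dir, paste0("g", run, ".fa")))
    write_sim_gff3(sim, file.path(dir, paste0("a", run, ".gff3")))
  }
  expect_identical(readLines(file.path(dir, "g1.fa")),
                   readLines(file.path(dir, "g2.fa")))
  expect_identical(readLines(file.path(dir, "a1.gff3")),
                   readLines(file.path(dir, "a2.gff3")))
})

test_that("annotation holds one gene feature per locus and gene", {
  cfg <- small_cfg()
  sim <- simulate_genome(cfg)
  dir <- withr::local_tempdir()
  gff <- write_sim_gff3(sim, file.path(dir, "a.gff3"))
  lines <- readLines(gff)
  expect_equal(sum(grepl("\tgene\t", lines, fixed = TRUE)),
               nrow(cfg$noncoding_loci) + cfg$n_coding_genes)
  idx <- load_annotation(gff)  # round-trips through the annotate module
  expect_equal(length(idx$features),
               nrow(cfg$noncoding_loci) + cfg$n_coding_genes)
})

test_that("feature placements never overlap", {
  sim <- simulate_genome(small_cfg(seed = 8L))
  f <- sim$features
  for (ch in unique(f$chrom)) {
    fc <- f[f$chrom == ch, ]
    fc <- fc[order(fc$start), ]
    if (nrow(fc) > 1L) {
      # interval-overlap oracle: each start after the previous end
      expect_true(all(fc$start[-1] >= fc$end[-nrow(fc)]))
    }
  }
})

test_that("cores sit inside their loci and match the genome sequence", {
  sim <- simulate_genome(small_cfg(seed = 13L))
  f <- sim$features
  for (j in seq_len(nrow(sim$cores))) {
    co <- sim$cores[j, ]
    locus <- f[f$feature_id == co$locus_id, ]
    expect_true(co$start >= locus$start && co$end <= locus$end)
    g <- substr(sim$genome[[co$chrom]], co$start + 1L, co$end)
    expect_equal(co$sequence, if (co$strand == "-") revcomp(g) else g)
  }
})

test_that("explicit core sequences are embedded verbatim", {
  core <- strrep("ACGGT", 4)  # 20 nt
  cfg <- small_cfg(core_sequences = c(core, NA, NA, NA, NA),
                   core_lengths = c(20L, 22L, 20L, 23L, 24L))
  sim <- simulate_genome(cfg)
  expect_equal(sim$cores$sequence[1], core)
  rd <- simulate_reads(sim, "s1", seed = 99L)
  fam <- rd[rd$source == "core_1", ]
  expect_true(all(grepl(core, fam$sequence, fixed = TRUE)))
})

test_that("zero raggedness collapses every family read onto its core", {
  cfg <- small_cfg(raggedness = 0L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, "s1", seed = 21L)
  for (j in seq_len(nrow(sim$cores))) {
    fam <- rd$sequence[rd$source == sim$cores$core_id[j]]
    expect_true(all(fam == sim$cores$sequence[j]))
  }
})

test_that("family reads contain their core and include the bare core", {
  sim <- simulate_genome(small_cfg())
  rd <- simulate_reads(sim, "s1", seed = 31L)
  for (j in seq_len(nrow(sim$cores))) {
    core <- sim$cores$sequence[j]
    fam <- rd$sequence[rd$source == sim$cores$core_id[j]]
    expect_true(all(grepl(core, fam, fixed = TRUE)))
    expect_true(core %in% fam)
  }
})

test_that("planted fractions are recovered within a binomial 99% CI", {
  cfg <- small_cfg(n_reads = 10000L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, "s1", seed = 77L)
  for (j in seq_len(nrow(sim$cores))) {
    f <- cfg$core_fractions[j]
    obs <- sum(rd$source == sim$cores$core_id[j])
    ci <- stats::qbinom(c(0.005, 0.995), cfg$n_reads, f)
    expect_true(obs >= ci[1] && obs <= ci[2],
                info = sprintf("core %d: %d outside [%d, %d]",
                               j, obs, ci[1], ci[2]))
  }
})

test_that("SAM records are coordinate-consistent with the reference", {
  dir <- withr::local_tempdir()
  sim <- simulate_genome(small_cfg())
  rd <- simulate_reads(sim, "s1", seed = 41L, n_reads = 500L)
  sam <- write_sim_sam(rd, sim, file.path(dir, "s1.sam"))
  body <- grep("^@", readLines(sam), invert = TRUE, value = TRUE)
  fields <- strsplit(body, "\t", fixed = TRUE)
  for (f in fields[1:200]) {
    pos <- as.integer(f[4]); seq <- f[10]
    ref <- substr(sim$genome[[f[3]]], pos, pos + nchar(seq) - 1L)
    expect_equal(seq, ref)  # stored in reference orientation
  }
  # and the loader restores read orientation
  back <- load_reads(sam, "s1", min_len = 1L, max_len = 100L)
  merged <- merge(rd, back, by = "query_name",
                  suffixes = c(".sim", ".loaded"))
  expect_equal(nrow(merged), nrow(rd))
  expect_equal(merged$sequence.loaded, merged$sequence.sim)
  expect_equal(merged$start.loaded, merged$start.sim)
})

test_that("depletion thins targeted families and preserves the rest", {
  cfg <- small_cfg(n_reads = 10000L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, "s1", seed = 55L)
  top_core <- sim$cores$sequence[1]
  dep <- simulate_depletion(rd, top_core, factor = 1000, seed = 56L)
  expect_equal(nrow(dep), nrow(rd))  # resampled to constant depth

  fam_frac <- mean(dep$source == sim$cores$core_id[1])
  expect_lt(fam_frac, 0.001 + 0.003)  # 30% family reduced ~1000-fold

  # untargeted relative gene proportions preserved (chi-square oracle)
  genes_before <- table(rd$source[startsWith(rd$source, "gene_")])
  genes_after <- table(factor(dep$source[startsWith(dep$source, "gene_")],
                              levels = names(genes_before)))
  keep <- genes_before >= 20
  p <- stats::chisq.test(as.numeric(genes_after[keep]),
                         p = as.numeric(genes_before[keep]) /
                           sum(genes_before[keep]))$p.value
  expect_gt(p, 0.001)
})

test_that("an extreme depletion factor removes targeted families", {
  cfg <- small_cfg(n_reads = 5000L)
  sim <- simulate_genome(cfg)
  rd <- simulate_reads(sim, "s1", seed = 61L)
  dep <- simulate_depletion(rd, sim$cores$sequence, factor = 1e9,
                            seed = 62L)
  expect_equal(sum(dep$source %in% sim$cores$core_id), 0L)
})

test_that("planted fraction sums above 0.95 are rejected", {
  expect_error(sim_config(core_fractions = c(0.6, 0.4)), "0.95")
})
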