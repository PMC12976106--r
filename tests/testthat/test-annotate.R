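make_read_row <- function(chrom, start0, end0, strand = "+",
                          sample_id = "s1") {
  data.frame(query_name = sprintf("r_%s_%d", chrom, start0),
             sequence = strrep("A", end0 - start0), chrom = chrom,
             start = start0, end = end0, strand = strand,
             sample_id = sample_id, stringsAsFactors = FALSE)
}

test_that("GFF3 coordinates convert to 0-based half-open and biotypes classify", {
  dir <- withr::local_tempdir()
  idx <- load_annotation(write_toy_gff3(file.path(dir, "toy.gff3")))
  f <- idx$features
  rrna <- f[S4Vectors::mcols(f)$feature_id == "rrna1"]
  expect_equal(BiocGenerics::start(rrna) - 1L, 100L)  # 0-based inclusive
  expect_equal(BiocGenerics::end(rrna), 200L)         # 0-based exclusive
  expect_false(S4Vectors::mcols(rrna)$coding)
  expect_true(S4Vectors::mcols(f)$coding[
    S4Vectors::mcols(f)$feature_id == "pc1"])
})

test_that("GTF dialect is auto-detected and rRNA classified non-coding", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "toy.gtf")
  writeLines(c(
    'chr1\ttoy\tgene\t101\t200\t.\t+\t.\tgene_id "g1"; gene_biotype "rRNA";',
    'chr1\ttoy\tgene\t501\t900\t.\t+\t.\tgene_id "g2"; gene_biotype "protein_coding";'
  ), path)
  idx <- load_annotation(path)
  bt <- S4Vectors::mcols(idx$features)$biotype
  expect_setequal(bt, c("rRNA", "protein_coding"))
  expect_equal(sum(S4Vectors::mcols(idx$features)$coding), 1L)
})

test_that("unknown biotypes default to non-coding with a warning", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "odd.gff3")
  writeLines(c("##gff-version 3",
               paste0("chr1\ttoy\tgene\t101\t200\t.\t+\t.\t",
                      "ID=x1;gene_id=x1;gene_biotype=weird_rna")), path)
  expect_warning(idx <- load_annotation(path), "weird_rna")
  expect_false(S4Vectors::mcols(idx$features)$coding)
  cl <- classify_reads(make_read_row("chr1", 120L, 145L), idx)
  expect_equal(cl$category, "noncoding")
})

test_that("classification follows non-coding precedence and handles misses", {
  dir <- withr::local_tempdir()
  idx <- load_annotation(write_toy_gff3(file.path(dir, "toy.gff3")))
  reads <- rbind(
    make_read_row("chr1", 120L, 145L),   # inside rRNA -> noncoding
    make_read_row("chr1", 1420L, 1445L), # pc1 + embedded snoRNA -> noncoding
    make_read_row("chr1", 1100L, 1125L), # pc1 only -> mRNA
    make_read_row("chr1", 5000L, 5025L), # no feature -> unassigned
    make_read_row("chr2", 550L, 575L),   # tRNA -> noncoding
    make_read_row("chr2", 2100L, 2125L)  # pc3 -> mRNA
  )
  cl <- classify_reads(reads, idx)
  expect_equal(cl$category, c("noncoding", "noncoding", "mRNA",
                              "unassigned", "noncoding", "mRNA"))
  expect_equal(cl$biotype[1], "rRNA")
  expect_equal(cl$gene_id[3], "pc1")

  expect_warning(
    off <- classify_reads(make_read_row("chrX", 10L, 35L), idx),
    "absent")
  expect_equal(off$category, "unassigned")
})

test_that("category counts partition the input and ignore read order", {
  dir <- withr::local_tempdir()
  idx <- load_annotation(write_toy_gff3(file.path(dir, "toy.gff3")))
  set.seed(11)
  starts <- sample(0:3500, 80L)
  reads <- do.call(rbind, lapply(starts, function(s) {
    make_read_row("chr1", s, s + 25L)
  }))
  reads$query_name <- sprintf("q%03d", seq_len(nrow(reads)))
  cl <- classify_reads(reads, idx)
  expect_equal(nrow(cl), 80L)
  expect_equal(sum(table(cl$category)), 80L)

  perm <- sample.int(nrow(reads))
  cl2 <- classify_reads(reads[perm, ], idx)
  expect_equal(cl2$category[order(perm)], cl$category)
})

test_that("an empty non-coding set means no read is classified noncoding", {
  dir <- withr::local_tempdir()
  idx <- load_annotation(
    write_toy_gff3(file.path(dir, "toy.gff3")),
    biotypes = list(coding = c("protein_coding", "rRNA", "tRNA", "snoRNA"),
                    noncoding = character(0)),
    unknown_to_noncoding = FALSE)
  reads <- rbind(make_read_row("chr1", 120L, 145L),
                 make_read_row("chr1", 1100L, 1125L))
  cl <- classify_reads(reads, idx)
  expect_false(any(cl$category == "noncoding"))
})

test_that("stranded overlap requires matching strands", {
  dir <- withr::local_tempdir()
  idx <- load_annotation(write_toy_gff3(file.path(dir, "toy.gff3")))
  # sno1 is annotated on minus; a plus-strand read inside it
  plus_read <- make_read_row("chr1", 1420L, 1445L)
  expect_equal(classify_reads(plus_read, idx, stranded = FALSE)$category,
               "noncoding")
  expect_equal(classify_reads(plus_read, idx, stranded = TRUE)$category,
               "mRNA")  # only the plus/embedding pc1... sno1 no longer hits
})

test_that("classification summary fractions sum to one per sample", {
  cl <- make_classes(c("AAAA", "CCCC", "GGGG", "TTTT"),
                     sample_id = c("a", "a", "b", "b"),
                     category = c("mRNA", "noncoding", "mRNA", "unassigned"))
  s <- classification_summary(cl)
  sums <- tapply(s$fraction, s$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1))
})
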