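#' Simulation configuration
#'
#' Defines a fully deterministic synthetic test universe: a toy genome with
#' embedded non-coding loci and coding genes, a set of planted contaminant
#' cores with library fractions, and read-generation parameters. The
#' defaults emulate a typical ribosome-profiling contaminant landscape: a
#' handful of rRNA/tRNA/snoRNA fragment families dominating the library,
#' with planted fractions 0.30, 0.15, 0.08, 0.04 and 0.02 (59% contaminant
#' burden overall) and ragged 5'/3' fragment ends from imprecise nuclease
#' trimming.
#'
#' @param seed Integer seed; fully determines every simulated output.
#' @param n_chroms Number of chromosomes (default 2).
#' @param chrom_length Length of each chromosome in nt (default 100000).
#' @param noncoding_loci `data.frame` with columns `biotype` and `length`:
#'   one non-coding locus per row; contaminant cores are placed inside these
#'   loci in order (recycled if fewer loci than cores).
#' @param n_coding_genes Number of protein-coding genes (default 60).
#' @param gene_length Length of each coding gene (default 900 nt).
#' @param core_fractions Planted library fraction per contaminant core;
#'   must sum to at most 0.95.
#' @param core_lengths Length of each auto-generated core in nt (cores are
#'   cut from the simulated non-coding loci). Recycled to the number of
#'   fractions.
#' @param core_sequences Optional explicit core sequences (embedded into
#'   the loci); `NA` entries are auto-generated.
#' @param raggedness Maximum 5' and 3' extension of a fragment beyond its
#'   core, in nt (default 3).
#' @param read_len_range mRNA footprint length range (default `c(20, 32)`).
#' @param n_reads Reads per simulated library (default 20000).
#' @param depletion_factor Fold-reduction applied to targeted reads during
#'   in-silico depletion (default 1000).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 100000L,
                       noncoding_loci = data.frame(
                         biotype = c("rRNA", "rRNA", "rRNA", "tRNA",
                                     "snoRNA"),
                         length = c(3000L, 2000L, 1500L, 300L, 250L),
                         stringsAsFactors = FALSE),
                       n_coding_genes = 60L,
                       gene_length = 900L,
                       core_fractions = c(0.30, 0.15, 0.08, 0.04, 0.02),
                       core_lengths = c(21L, 22L, 20L, 23L, 24L),
                       core_sequences = NULL,
                       raggedness = 3L,
                       read_len_range = c(20L, 32L),
                       n_reads = 20000L,
                       depletion_factor = 1000) {
  if (sum(core_fractions) > 0.95) {
    stop("planted core fractions must sum to at most 0.95")
  }
  k <- length(core_fractions)
  core_lengths <- rep_len(core_lengths, k)
  if (is.null(core_sequences)) core_sequences <- rep(NA_character_, k)
  core_sequences <- rep_len(core_sequences, k)
  structure(list(seed = as.integer(seed), n_chroms = n_chroms,
                 chrom_length = chrom_length,
                 noncoding_loci = noncoding_loci,
                 n_coding_genes = n_coding_genes,
                 gene_length = gene_length,
                 core_fractions = core_fractions,
                 core_lengths = core_lengths,
                 core_sequences = core_sequences,
                 raggedness = raggedness,
                 read_len_range = read_len_range,
                 n_reads = n_reads,
                 depletion_factor = depletion_factor),
            class = "sim_config")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a toy genome and annotation
#'
#' Generates random chromosome sequences, places the configured non-coding
#' loci and coding genes without overlap, embeds (or cuts) one contaminant
#' core inside each designated non-coding locus, and records everything
#' with 0-based half-open coordinates. Strands are assigned at random so
#' both orientations are exercised downstream.
#'
#' @param config A `sim_config`.
#' @return A list of class `sim_genome` with `genome` (named character
#'   vector of chromosome sequences), `features` (`data.frame`: feature_id,
#'   chrom, start, end, strand, biotype, gene_id), `cores` (`data.frame`:
#'   core_id, sequence in transcript orientation, fraction, chrom, start,
#'   end, strand, locus_id) and `config`.
#' @export
simulate_genome <- function(config) {
  set.seed(config$seed)
  genome <- stats::setNames(
    vapply(seq_len(config$n_chroms), function(i) random_dna(config$chrom_length),
           character(1)),
    paste0("chr", seq_len(config$n_chroms)))

  loci <- config$noncoding_loci
  feats <- data.frame(
    feature_id = c(sprintf("ncrna_%02d", seq_len(nrow(loci))),
                   sprintf("gene_%03d", seq_len(config$n_coding_genes))),
    length = c(loci$length, rep(config$gene_length, config$n_coding_genes)),
    biotype = c(loci$biotype,
                rep("protein_coding", config$n_coding_genes)),
    stringsAsFactors = FALSE
  )
  n <- nrow(feats)
  feats$chrom <- rep_len(names(genome), n)
  feats$strand <- sample(c("+", "-"), n, replace = TRUE)
  margin <- 200L + config$raggedness

  # sequential placement with random gaps, per chromosome
  cursor <- stats::setNames(rep(margin, length(genome)), names(genome))
  starts <- integer(n)
  for (i in seq_len(n)) {
    ch <- feats$chrom[i]
    gap <- sample(100:400, 1L)
    s <- cursor[[ch]] + gap
    e <- s + feats$length[i]
    if (e + margin > nchar(genome[[ch]])) {
      stop("features exceed chromosome length; increase chrom_length")
    }
    starts[i] <- s
    cursor[[ch]] <- e
  }
  feats$start <- starts           # 0-based inclusive
  feats$end <- starts + feats$length
  feats$gene_id <- feats$feature_id

  # place one core inside each designated non-coding locus
  k <- length(config$core_fractions)
  locus_idx <- rep_len(seq_len(nrow(loci)), k)
  cores <- data.frame(core_id = sprintf("core_%d", seq_len(k)),
                      sequence = NA_character_,
                      fraction = config$core_fractions,
                      chrom = NA_character_, start = NA_integer_,
                      end = NA_integer_, strand = NA_character_,
                      locus_id = feats$feature_id[locus_idx],
                      stringsAsFactors = FALSE)
  used <- list()
  for (j in seq_len(k)) {
    f <- feats[locus_idx[j], ]
    len <- config$core_lengths[j]
    pad <- config$raggedness + 2L
    repeat {
      s <- sample((f$start + pad):(f$end - len - pad), 1L)
      clash <- any(vapply(used[[f$feature_id]] %||% list(), function(iv) {
        s < iv[2] + pad && iv[1] - pad < s + len
      }, logical(1)))
      if (!clash) break
    }
    used[[f$feature_id]] <- c(used[[f$feature_id]], list(c(s, s + len)))
    if (!is.na(config$core_sequences[j])) {
      core_seq <- toupper(config$core_sequences[j])
      stopifnot(nchar(core_seq) == len)
      insert <- if (f$strand == "-") revcomp(core_seq) else core_seq
      substr(genome[[f$chrom]], s + 1L, s + len) <- insert
    } else {
      g <- substr(genome[[f$chrom]], s + 1L, s + len)
      core_seq <- if (f$strand == "-") revcomp(g) else g
    }
    cores$sequence[j] <- core_seq
    cores$chrom[j] <- f$chrom
    cores$start[j] <- s
    cores$end[j] <- s + len
    cores$strand[j] <- f$strand
  }
  feats$length <- NULL
  structure(list(genome = genome, features = feats, cores = cores,
                 config = config),
            class = "sim_genome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate one aligned Ribo-Seq library
#'
#' Draws `n_reads` reads: contaminant fragments are the planted cores
#' extended by uniform ragged 5'/3' ends cut from the flanking genomic
#' sequence (so every family member contains its core as a substring), with
#' per-core read counts following the planted fractions via multinomial
#' sampling; the remaining reads are mRNA footprints drawn uniformly within
#' coding genes with lengths in `read_len_range` and per-gene abundances
#' from a seeded log-normal expression profile. The un-extended core itself
#' is always emitted at least once per family, so the grouping can recover
#' the exact core as the shortest member.
#'
#' @param sim A `sim_genome` from [simulate_genome()].
#' @param sample_id Sample identifier for the generated library.
#' @param seed Seed for this library (distinct per replicate).
#' @param n_reads Number of reads (defaults to the configured value).
#' @return A `data.frame` of aligned reads (columns of [load_reads()]) with
#'   an extra `source` column (core id or gene id) as ground-truth
#'   provenance. Sequences are in read (transcript) orientation.
#' @export
simulate_reads <- function(sim, sample_id, seed, n_reads = NULL) {
  config <- sim$config
  set.seed(seed)
  n_reads <- n_reads %||% config$n_reads
  k <- nrow(sim$cores)
  probs <- c(sim$cores$fraction, 1 - sum(sim$cores$fraction))
  counts <- as.integer(stats::rmultinom(1L, n_reads, probs))

  # stable per-gene expression profile derived from the genome seed
  genes <- sim$features[sim$features$biotype == "protein_coding", ,
                        drop = FALSE]
  gene_rng <- config$seed + 104729L  # decouple expression from placement
  expr <- local({
    set.seed(gene_rng)
    w <- stats::rlnorm(nrow(genes), meanlog = 0, sdlog = 1.2)
    w / sum(w)
  })

  parts <- vector("list", k + 1L)
  for (j in seq_len(k)) {
    nj <- counts[j]
    if (nj == 0L) {
      # guarantee family presence so recovery is well-defined
      nj <- 1L
    }
    a <- sample(0:config$raggedness, nj, replace = TRUE)
    b <- sample(0:config$raggedness, nj, replace = TRUE)
    a[1L] <- 0L; b[1L] <- 0L  # un-extended core always present
    co <- sim$cores[j, ]
    if (co$strand == "+") {
      s <- co$start - a; e <- co$end + b
    } else {
      s <- co$start - b; e <- co$end + a
    }
    parts[[j]] <- data.frame(chrom = co$chrom, start = s, end = e,
                             strand = co$strand, source = co$core_id,
                             stringsAsFactors = FALSE)
  }
  nm <- counts[k + 1L]
  if (nm > 0L) {
    gi <- sample.int(nrow(genes), nm, replace = TRUE, prob = expr)
    len <- sample(config$read_len_range[1]:config$read_len_range[2], nm,
                  replace = TRUE)
    s <- genes$start[gi] +
      floor(stats::runif(nm) * (genes$end[gi] - genes$start[gi] - len + 1))
    parts[[k + 1L]] <- data.frame(chrom = genes$chrom[gi], start = as.integer(s),
                                  end = as.integer(s + len),
                                  strand = genes$strand[gi],
                                  source = genes$gene_id[gi],
                                  stringsAsFactors = FALSE)
  }
  reads <- do.call(rbind, parts)
  ord <- sample.int(nrow(reads))  # shuffle so file order carries no signal
  reads <- reads[ord, , drop = FALSE]
  g <- vapply(seq_len(nrow(reads)), function(i) {
    substr(sim$genome[[reads$chrom[i]]], reads$start[i] + 1L, reads$end[i])
  }, character(1))
  reads$sequence <- ifelse(reads$strand == "-", revcomp(g), g)
  reads$query_name <- sprintf("%s_read_%06d", sample_id, seq_len(nrow(reads)))
  reads$sample_id <- sample_id
  rownames(reads) <- NULL
  reads[, c("query_name", "sequence", "chrom", "start", "end", "strand",
            "sample_id", "source")]
}

#' In-silico LNA depletion of a read set
#'
#' Emulates blocking during library amplification: every read whose
#' sequence contains a probe's target pattern as a substring is retained
#' with probability `1/factor`; survivors are then resampled with
#' replacement back to the original library size, mimicking a fixed
#' sequencing depth. The renormalisation is what makes the mRNA yield rise
#' when contaminants are blocked.
#'
#' @param reads Read `data.frame` (e.g. from [simulate_reads()]).
#' @param probes List of `lna_probe` objects (or character vector of target
#'   patterns, read orientation).
#' @param factor Fold-reduction for targeted reads (> 1).
#' @param seed Seed for the stochastic thinning and resampling.
#' @return A `data.frame` of the same shape with fresh `query_name`s.
#' @export
simulate_depletion <- function(reads, probes, factor, seed) {
  stopifnot(factor > 1)
  set.seed(seed)
  patterns <- if (is.character(probes)) probes
              else vapply(probes, `[[`, character(1), "target_pattern")
  targeted <- rep(FALSE, nrow(reads))
  for (p in patterns) {
    targeted <- targeted | grepl(p, reads$sequence, fixed = TRUE)
  }
  keep <- !targeted | stats::runif(nrow(reads)) < 1 / factor
  surv <- reads[keep, , drop = FALSE]
  if (nrow(surv) == 0L) stop("depletion removed every read")
  idx <- sample.int(nrow(surv), nrow(reads), replace = TRUE)
  out <- surv[idx, , drop = FALSE]
  out$query_name <- sprintf("%s_dep_%06d", out$sample_id, seq_len(nrow(out)))
  rownames(out) <- NULL
  out
}

#' Write simulated chromosomes to FASTA
#' @param sim A `sim_genome` (or named character vector of sequences).
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_sim_fasta <- function(sim, path) {
  genome <- if (inherits(sim, "sim_genome")) sim$genome else sim
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Write the simulated annotation to GFF3
#' @param sim A `sim_genome`.
#' @param path Output GFF3 path.
#' @return Invisibly, `path`.
#' @export
write_sim_gff3 <- function(sim, path) {
  f <- sim$features
  lines <- c("##gff-version 3",
             sprintf("%s\tribosweep_sim\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;gene_biotype=%s",
                     f$chrom, f$start + 1L, f$end, f$strand,
                     f$feature_id, f$gene_id, f$biotype))
  writeLines(lines, path)
  invisible(path)
}

#' Write reads as a coordinate-correct SAM file
#'
#' Sequences are stored in reference orientation with FLAG 16 for
#' minus-strand alignments, matching aligner output, so the loader's
#' orientation handling is exercised end to end.
#'
#' @param reads Read `data.frame` with genomic coordinates.
#' @param sim A `sim_genome` (for the header), or a named vector of
#'   chromosome lengths.
#' @param path Output SAM path.
#' @return Invisibly, `path`.
#' @export
write_sim_sam <- function(reads, sim, path) {
  lens <- if (inherits(sim, "sim_genome")) {
    vapply(sim$genome, nchar, integer(1))
  } else sim
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(lens), as.integer(lens)))
  neg <- reads$strand == "-"
  seq_ref <- reads$sequence
  if (any(neg)) seq_ref[neg] <- revcomp(seq_ref[neg])
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  reads$query_name, ifelse(neg, 16L, 0L), reads$chrom,
                  reads$start + 1L, nchar(reads$sequence), seq_ref,
                  strrep("I", nchar(reads$sequence)))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write reads as FASTQ
#' @param reads Read `data.frame`.
#' @param path Output FASTQ path.
#' @return Invisibly, `path`.
#' @export
write_sim_fastq <- function(reads, path) {
  lines <- as.vector(rbind(paste0("@", reads$query_name),
                           reads$sequence,
                           "+",
                           strrep("I", nchar(reads$sequence))))
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete two-arm experiment on disk
#'
#' Generates the genome and annotation, simulates undepleted replicate
#' libraries, designs probes against the true planted cores, applies
#' in-silico depletion to produce the depleted arm, and writes FASTA, GFF3,
#' per-sample SAM and FASTQ, a sample manifest and a ground-truth JSON into
#' `outdir`.
#'
#' @param config A `sim_config`.
#' @param outdir Output directory.
#' @param n_replicates Replicates per arm (default 2).
#' @param depleted_arm Also simulate an LNA-depleted arm (default `TRUE`).
#' @return A list with `manifest` (path), `annotation` (path), `fasta`
#'   (path), `sim` (the `sim_genome`), `truth` (list) and `reads` (named
#'   list of read frames).
#' @export
simulate_experiment <- function(config, outdir, n_replicates = 2L,
                                depleted_arm = TRUE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_genome(config)
  fasta <- file.path(outdir, "genome.fa")
  gff <- file.path(outdir, "annotation.gff3")
  write_sim_fasta(sim, fasta)
  write_sim_gff3(sim, gff)

  probes <- lapply(seq_len(nrow(sim$cores)), function(j) {
    design_probe(sim$cores$sequence[j],
                 name = sprintf("LNA_Top_%d", j))
  })

  rows <- list(); reads <- list()
  for (r in seq_len(n_replicates)) {
    sid <- sprintf("undepleted_%d", r)
    rd <- simulate_reads(sim, sid, seed = config$seed + 1000L * r)
    sam <- file.path(outdir, paste0(sid, ".sam"))
    write_sim_sam(rd, sim, sam)
    write_sim_fastq(rd, file.path(outdir, paste0(sid, ".fastq")))
    rows[[sid]] <- data.frame(sample_id = sid, path = basename(sam),
                              condition = "control", depleted = FALSE,
                              stringsAsFactors = FALSE)
    reads[[sid]] <- rd
  }
  if (depleted_arm) {
    for (r in seq_len(n_replicates)) {
      sid <- sprintf("depleted_%d", r)
      base <- simulate_reads(sim, sid, seed = config$seed + 5000L * r + 17L)
      rd <- simulate_depletion(base, probes, config$depletion_factor,
                               seed = config$seed + 9000L * r + 29L)
      sam <- file.path(outdir, paste0(sid, ".sam"))
      write_sim_sam(rd, sim, sam)
      write_sim_fastq(rd, file.path(outdir, paste0(sid, ".fastq")))
      rows[[sid]] <- data.frame(sample_id = sid, path = basename(sam),
                                condition = "control", depleted = TRUE,
                                stringsAsFactors = FALSE)
      reads[[sid]] <- rd
    }
  }
  manifest <- file.path(outdir, "manifest.tsv")
  utils::write.table(do.call(rbind, rows), manifest, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- list(cores = sim$cores,
                probes = lapply(probes, function(p) {
                  list(name = p$name, target = p$target_pattern,
                       rendered = render_probe(p))
                }),
                depletion_factor = config$depletion_factor,
                seed = config$seed)
  jsonlite::write_json(truth, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  list(manifest = manifest, annotation = gff, fasta = fasta,
       sim = sim, truth = truth, reads = reads)
}
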