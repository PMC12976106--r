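# Shared fixtures: all built in code at test time.

# Build a classified-read frame directly (bypasses file I/O).
make_classes <- function(sequence, sample_id = "s1",
                         category = "unassigned", biotype = NA_character_,
                         gene_id = NA_character_) {
  n <- length(sequence)
  data.frame(query_name = sprintf("r%04d", seq_len(n)),
             sequence = sequence,
             chrom = rep_len("chr1", n),
             start = seq_len(n), end = seq_len(n) + 1L,
             strand = rep_len("+", n),
             sample_id = rep_len(sample_id, n),
             category = rep_len(category, n),
             biotype = rep_len(biotype, n),
             gene_id = rep_len(gene_id, n),
             n_features = rep_len(1L, n),
             stringsAsFactors = FALSE)
}

# Build collapsed reads from a named count spec: list(sampleA = c(SEQ = n)).
make_collapsed <- function(counts_by_sample, category = NULL,
                           biotype = NULL) {
  seqs <- sort(unique(unlist(lapply(counts_by_sample, names))))
  samples <- names(counts_by_sample)
  m <- matrix(0L, length(seqs), length(samples),
              dimnames = list(NULL, samples))
  for (s in samples) {
    v <- counts_by_sample[[s]]
    m[match(names(v), seqs), s] <- as.integer(v)
  }
  if (is.null(category)) category <- rep("noncoding", length(seqs))
  if (is.null(biotype)) biotype <- rep("rRNA", length(seqs))
  ribosweep:::new_collapsed(seqs, m, category, biotype)
}

# Random collapsed-read sets over a small alphabet so substring containment
# occurs often; deterministic per seed.
random_collapsed <- function(seed, n = 200L, n_samples = 2L,
                             len_range = c(5L, 14L), alphabet = c("A", "C",
                                                                  "G", "T")) {
  set.seed(seed)
  seqs <- character(0)
  while (length(seqs) < n) {
    len <- sample(len_range[1]:len_range[2], 1L)
    seqs <- unique(c(seqs, paste(sample(alphabet, len, replace = TRUE),
                                 collapse = "")))
  }
  seqs <- seqs[seq_len(n)]
  samples <- paste0("s", seq_len(n_samples))
  m <- matrix(sample(1:50, n * n_samples, replace = TRUE), n, n_samples,
              dimnames = list(NULL, samples))
  ord <- order(seqs)
  ribosweep:::new_collapsed(seqs[ord], m[ord, , drop = FALSE],
                            sample(c("noncoding", "mRNA"), n, replace = TRUE),
                            sample(c("rRNA", "tRNA", "protein_coding"), n,
                                   replace = TRUE))
}

# Independent brute-force reference for the greedy containment grouping:
# explicit per-read loops and regexpr(), list-based bookkeeping. Returns a
# canonical representation for comparison with the package implementation.
naive_aggregate <- function(patterns, search_set) {
  pool <- lapply(seq_along(search_set$sequence), function(i) {
    list(seq = search_set$sequence[i],
         counts = search_set$counts[i, , drop = TRUE])
  })
  pat_df <- data.frame(seq = patterns$sequence, total = patterns$total,
                       stringsAsFactors = FALSE)
  pat_df <- pat_df[order(nchar(pat_df$seq), -pat_df$total, pat_df$seq), ,
                   drop = FALSE]
  groups <- list()
  for (p in pat_df$seq) {
    still_there <- FALSE
    for (r in pool) if (identical(r$seq, p)) { still_there <- TRUE; break }
    if (!still_there) next
    members <- list(); rest <- list()
    for (r in pool) {
      if (regexpr(p, r$seq, fixed = TRUE)[1] > 0) {
        members[[length(members) + 1L]] <- r
      } else {
        rest[[length(rest) + 1L]] <- r
      }
    }
    cnt <- Reduce(`+`, lapply(members, `[[`, "counts"))
    groups[[length(groups) + 1L]] <- list(
      pattern = p,
      member_seqs = sort(vapply(members, `[[`, character(1), "seq")),
      counts = cnt, total = sum(cnt))
    pool <- rest
  }
  totals <- vapply(groups, `[[`, numeric(1), "total")
  pats <- vapply(groups, `[[`, character(1), "pattern")
  groups <- groups[order(-totals, pats)]
  list(groups = groups,
       ungrouped_seqs = sort(vapply(pool, `[[`, character(1), "seq")))
}

# Canonicalise an aggregation_result the same way for comparison.
canonical_result <- function(result) {
  list(groups = lapply(result$groups, function(g) {
    list(pattern = g$pattern,
         member_seqs = sort(result$collapsed$sequence[g$member_idx]),
         counts = g$counts, total = g$total)
  }),
  ungrouped_seqs = sort(result$collapsed$sequence[result$ungrouped]))
}

# Hand-written SAM fixture. reads: data.frame(qname, flag, chrom, pos1, seq).
write_test_sam <- function(reads, path,
                           sq = c(chr1 = 10000L, chr2 = 10000L)) {
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sq), sq))
  body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$chrom, reads$pos1,
                  nchar(reads$seq), reads$seq, strrep("I", nchar(reads$seq)))
  writeLines(c(header, body), path)
  path
}

# Toy six-feature annotation exercising coding/noncoding precedence.
write_toy_gff3 <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t101\t200\t.\t+\t.\tID=rrna1;gene_id=rrna1;gene_biotype=rRNA",
    "chr1\ttoy\tgene\t1001\t2000\t.\t+\t.\tID=pc1;gene_id=pc1;gene_biotype=protein_coding",
    "chr1\ttoy\tgene\t1401\t1500\t.\t-\t.\tID=sno1;gene_id=sno1;gene_biotype=snoRNA",
    "chr1\ttoy\tgene\t3001\t3600\t.\t-\t.\tID=pc2;gene_id=pc2;gene_biotype=protein_coding",
    "chr2\ttoy\tgene\t501\t700\t.\t+\t.\tID=trna1;gene_id=trna1;gene_biotype=tRNA",
    "chr2\ttoy\tgene\t2001\t2900\t.\t+\t.\tID=pc3;gene_id=pc3;gene_biotype=protein_coding"
  ), path)
  path
}

random_target <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
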