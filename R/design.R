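#' Design an LNA blocker probe against a contaminant target
#'
#' Builds a blocker oligonucleotide following the alternating architecture:
#' DNA and LNA nucleotides strictly alternate, beginning (position 1) with a
#' DNA nucleotide, so LNA residues sit at all even positions. The 3' end is
#' phosphorylated by default so the blocker cannot prime extension. Targets
#' longer than `max_len` are trimmed to the window whose GC fraction is
#' closest to 0.5 (ties: leftmost), encoding standard primer-design
#' considerations.
#'
#' @param target Target DNA sequence (a contaminant group pattern); must be
#'   at least `min_len` long and contain no N.
#' @param min_len Minimum probe length (default 14 nt, the specificity floor
#'   recommended for a genome the size of Arabidopsis).
#' @param max_len Maximum probe length (default 20 nt).
#' @param orientation `"antisense"` (default; probe is the reverse complement
#'   of the target, hybridising to the read-sense strand) or `"sense"`.
#'   Blocking either strand of the amplicon suppresses amplification, so
#'   both orientations are effective.
#' @param name Probe name for order sheets.
#' @param phos_3prime Append a 3'-phosphate (default `TRUE`).
#' @return An object of class `lna_probe`: list with `name`,
#'   `target_pattern`, `probe_sequence`, `lna_positions` (1-based, all even),
#'   `phos_3prime`, `orientation` and `qc` (see [qc_probe()]).
#' @export
design_probe <- function(target, min_len = 14L, max_len = 20L,
                         orientation = c("antisense", "sense"),
                         name = "LNA_probe", phos_3prime = TRUE) {
  orientation <- match.arg(orientation)
  target <- toupper(target)
  if (grepl("[^ACGT]", target)) {
    stop("target contains non-ACGT characters (N is not allowed): ", target)
  }
  if (nchar(target) < min_len) {
    stop("target is ", nchar(target), " nt but the minimum probe length is ",
         min_len, "; choose a longer target group pattern")
  }
  full <- if (orientation == "antisense") revcomp(target) else target
  probe <- pick_window(full, max_len)
  lna <- seq(2L, nchar(probe), by = 2L)
  p <- structure(list(name = name, target_pattern = target,
                      probe_sequence = probe,
                      lna_positions = lna,
                      phos_3prime = phos_3prime,
                      orientation = orientation,
                      qc = NULL),
                 class = "lna_probe")
  p$qc <- qc_probe(p)
  p
}

# max_len-wide window with GC fraction closest to 0.5; ties -> leftmost
pick_window <- function(seq, max_len) {
  n <- nchar(seq)
  if (n <= max_len) return(seq)
  starts <- seq_len(n - max_len + 1L)
  gc <- vapply(starts, function(s) {
    w <- substr(seq, s, s + max_len - 1L)
    gc_fraction(w)
  }, numeric(1))
  best <- starts[which.min(abs(gc - 0.5))]
  substr(seq, best, best + max_len - 1L)
}

gc_fraction <- function(x) {
  n <- nchar(x)
  if (n == 0L) return(NA_real_)
  (n - nchar(gsub("[GCgc]", "", x))) / n
}

max_homopolymer <- function(x) {
  r <- rle(strsplit(x, "", fixed = TRUE)[[1L]])
  if (length(r$lengths) == 0L) 0L else max(r$lengths)
}

#' Primer-style quality checks for an LNA probe
#'
#' Computes the GC fraction and longest homopolymer run of the probe
#' sequence, and optionally counts exact occurrences of the target pattern
#' (both strands) in a reference FASTA as a specificity check. Flags are
#' raised — as warnings in the record, not errors — when the GC fraction is
#' outside \[0.4, 0.7\] or a homopolymer exceeds 4 nt.
#'
#' @param probe An `lna_probe`.
#' @param reference Optional path to a FASTA file for specificity counting.
#' @return A list with `gc_fraction`, `max_homopolymer`, `specificity_hits`
#'   (`NA` when no reference given) and `flags` (character vector).
#' @export
qc_probe <- function(probe, reference = NULL) {
  seq <- probe$probe_sequence
  gc <- gc_fraction(seq)
  hp <- max_homopolymer(seq)
  flags <- character(0)
  if (gc < 0.4 || gc > 0.7) {
    flags <- c(flags, sprintf("gc_fraction %.3f outside [0.4, 0.7]", gc))
  }
  if (hp > 4L) {
    flags <- c(flags, sprintf("homopolymer run of %d nt exceeds 4", hp))
  }
  hits <- NA_integer_
  if (!is.null(reference)) {
    ref <- Biostrings::readDNAStringSet(reference)
    target <- Biostrings::DNAString(probe$target_pattern)
    fwd <- sum(Biostrings::vcountPattern(target, ref))
    rev <- sum(Biostrings::vcountPattern(
      Biostrings::reverseComplement(target), ref))
    hits <- fwd + rev
  }
  list(gc_fraction = gc, max_homopolymer = hp,
       specificity_hits = hits, flags = flags)
}

#' Render a probe in order-sheet notation
#'
#' Each LNA base is prefixed with `+` (the common vendor plain-text
#' notation) and a `/3Phos/` suffix marks the 3'-phosphate.
#'
#' @param probe An `lna_probe`.
#' @return A single string, e.g. `"G+CC+TG+GG+TG+TC+AC+A/3Phos/"`.
#' @export
render_probe <- function(probe) {
  bases <- strsplit(probe$probe_sequence, "", fixed = TRUE)[[1L]]
  pre <- ifelse(seq_along(bases) %in% probe$lna_positions, "+", "")
  out <- paste0(paste0(pre, bases), collapse = "")
  if (isTRUE(probe$phos_3prime)) out <- paste0(out, "/3Phos/")
  out
}

#' @export
print.lna_probe <- function(x, ...) {
  cat(x$name, " (", nchar(x$probe_sequence), " nt, ", x$orientation, "): ",
      render_probe(x), "\n", sep = "")
  invisible(x)
}

#' Design probes for the top contaminant groups
#'
#' Walks the ranked groups of an aggregation result and designs one probe
#' per eligible group until `n_probes` probes exist. Groups whose pattern is
#' shorter than `min_len` or contains N are skipped with a recorded reason
#' and the next group is promoted.
#'
#' @param result An `aggregation_result` (or a groups table from
#'   [groups_table()]).
#' @param n_probes Number of probes to design (default 5).
#' @inheritParams design_probe
#' @return A list with `probes` (list of `lna_probe`, named `LNA_Top_<i>`)
#'   and `skipped` (`data.frame` of rank, pattern, reason).
#' @export
design_probe_set <- function(result, n_probes = 5L, min_len = 14L,
                             max_len = 20L,
                             orientation = c("antisense", "sense")) {
  orientation <- match.arg(orientation)
  tab <- if (inherits(result, "aggregation_result")) groups_table(result)
         else result
  if (nrow(tab) == 0L) stop("no groups available for probe design")
  probes <- list()
  skipped <- data.frame(rank = integer(0), pattern = character(0),
                        reason = character(0), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(tab))) {
    if (length(probes) >= n_probes) break
    pat <- tab$pattern[i]
    res <- tryCatch(
      design_probe(pat, min_len = min_len, max_len = max_len,
                   orientation = orientation,
                   name = sprintf("LNA_Top_%d", length(probes) + 1L)),
      error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped <- rbind(skipped, data.frame(rank = tab$rank[i], pattern = pat,
                                           reason = res,
                                           stringsAsFactors = FALSE))
    } else {
      res$target_rank <- tab$rank[i]
      probes[[res$name]] <- res
    }
  }
  if (length(probes) == 0L) stop("no group pattern was eligible for design")
  list(probes = probes, skipped = skipped)
}

#' Write an order sheet for a probe set
#'
#' @param probe_set Result of [design_probe_set()] or a list of `lna_probe`.
#' @param path Output TSV path.
#' @return Invisibly, the order-sheet `data.frame` (name, rendered sequence,
#'   length, GC%, target group rank, target pattern, QC flags).
#' @export
write_order_sheet <- function(probe_set, path) {
  probes <- if (!is.null(probe_set$probes)) probe_set$probes else probe_set
  df <- do.call(rbind, lapply(probes, function(p) {
    data.frame(name = p$name,
               sequence = render_probe(p),
               length = nchar(p$probe_sequence),
               gc_percent = round(100 * p$qc$gc_fraction, 1),
               target_rank = if (is.null(p$target_rank)) NA_integer_
                             else p$target_rank,
               target_pattern = p$target_pattern,
               orientation = p$orientation,
               qc_flags = paste(p$qc$flags, collapse = "; "),
               stringsAsFactors = FALSE)
  }))
  rownames(df) <- NULL
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
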