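#' Load a sample manifest
#'
#' Reads a TSV or CSV manifest describing the alignment files of an
#' experiment. The manifest must contain the header columns `sample_id`,
#' `path`, `condition` and `depleted`; row order is preserved.
#'
#' @param path Path to a TSV or CSV file (delimiter auto-detected from the
#'   header line).
#' @param check_paths Verify that every alignment file exists and is readable
#'   (default `TRUE`). Disable for manifests describing in-memory runs.
#' @return A `data.frame` of class `sample_manifest` with columns
#'   `sample_id` (character), `path` (character), `condition` (character)
#'   and `depleted` (logical). Relative paths are resolved against the
#'   directory containing the manifest.
#' @export
load_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "",
                          quote = "\"")
  required <- c("sample_id", "path", "condition", "depleted")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop("manifest is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    warning("manifest contains no samples (header only)")
  }
  df$sample_id <- as.character(df$sample_id)
  df$path <- as.character(df$path)
  df$condition <- as.character(df$condition)
  df$depleted <- as.logical(df$depleted)
  if (anyNA(df$depleted)) {
    stop("manifest column 'depleted' must be TRUE/FALSE")
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0L) {
    stop("duplicate sample_id in manifest: ", paste(dup, collapse = ", "))
  }
  # resolve paths relative to the manifest location
  base <- dirname(normalizePath(path))
  rel <- !grepl("^(/|[A-Za-z]:)", df$path) & nzchar(df$path)
  df$path[rel] <- file.path(base, df$path[rel])
  if (check_paths) {
    for (i in seq_len(nrow(df))) {
      if (!file.exists(df$path[i])) {
        stop("alignment file for sample '", df$sample_id[i],
             "' (manifest row ", i, ") not found: ", df$path[i])
      }
    }
  }
  class(df) <- c("sample_manifest", "data.frame")
  df
}

#' Load aligned reads from a BAM or SAM file
#'
#' Loads mapped, primary, non-supplementary alignments and applies the
#' footprint length filter: only reads whose sequence length `L` satisfies
#' `min_len <= L <= max_len` are retained (both bounds inclusive). Each
#' query name contributes at most one record (the first primary alignment
#' wins). Sequences of reverse-strand alignments are reverse-complemented
#' back to read orientation, i.e. the fragment as it was sequenced.
#'
#' @param path Path to a BAM or SAM file. SAM text is converted on the fly.
#' @param sample_id Sample identifier attached to every record.
#' @param min_len,max_len Inclusive read-length bounds (defaults 20 and 30 nt,
#'   the ribosome-footprint size window after gel excision).
#' @return A `data.frame` with columns `query_name`, `sequence` (uppercase,
#'   read orientation), `chrom`, `start` (0-based inclusive), `end` (0-based
#'   exclusive), `strand` and `sample_id`.
#' @export
load_reads <- function(path, sample_id, min_len = 20L, max_len = 30L) {
  stopifnot(min_len <= max_len, min_len >= 1L)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (tolower(tools::file_ext(path)) == "sam") {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag, what = c("qname", "seq"))
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  if (length(aln) == 0L) {
    warning("no mapped primary alignments in ", path)
    return(empty_reads(sample_id))
  }
  mc <- S4Vectors::mcols(aln)
  if (any(BiocGenerics::width(mc$seq) == 0L)) {
    stop("alignment records without sequence in ", path)
  }
  seqs <- mc$seq
  # BAM stores sequences in reference orientation; restore read orientation
  neg <- as.character(BiocGenerics::strand(aln)) == "-"
  if (any(neg)) {
    seqs[neg] <- Biostrings::reverseComplement(seqs[neg])
  }
  seq_chr <- toupper(as.character(seqs))
  len <- nchar(seq_chr)
  keep <- len >= min_len & len <= max_len
  keep[keep] <- !duplicated(mc$qname[keep])
  df <- data.frame(
    query_name = mc$qname[keep],
    sequence = seq_chr[keep],
    chrom = as.character(GenomeInfoDb::seqnames(aln))[keep],
    start = BiocGenerics::start(aln)[keep] - 1L,
    end = BiocGenerics::end(aln)[keep],
    strand = as.character(BiocGenerics::strand(aln))[keep],
    sample_id = sample_id,
    stringsAsFactors = FALSE
  )
  rownames(df) <- NULL
  df
}

empty_reads <- function(sample_id = character(0)) {
  data.frame(query_name = character(0), sequence = character(0),
             chrom = character(0), start = integer(0), end = integer(0),
             strand = character(0),
             sample_id = character(0), stringsAsFactors = FALSE)
}

#' Load reads for every sample in a manifest
#'
#' @param manifest A `sample_manifest` from [load_manifest()].
#' @inheritParams load_reads
#' @return A single `data.frame` of reads (see [load_reads()]) concatenated
#'   over samples, in manifest order.
#' @export
load_manifest_reads <- function(manifest, min_len = 20L, max_len = 30L) {
  parts <- lapply(seq_len(nrow(manifest)), function(i) {
    load_reads(manifest$path[i], manifest$sample_id[i],
               min_len = min_len, max_len = max_len)
  })
  do.call(rbind, c(parts, list(make.row.names = FALSE)))
}

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
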