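#' Default biotype classification
#'
#' Contaminants in ribosome-profiling libraries are fragments of abundant
#' non-coding RNAs, so classification favours sensitivity: any biotype not
#' listed as coding counts as non-coding by default.
#'
#' @return A list with character vectors `coding` and `noncoding`.
#' @export
default_biotypes <- function() {
  list(
    coding = c("protein_coding", "mRNA", "CDS"),
    noncoding = c("rRNA", "tRNA", "snoRNA", "snRNA", "miRNA", "ncRNA",
                  "lncRNA", "antisense_long_noncoding_rna",
                  "novel_transcribed_region")
  )
}

#' Load a genome annotation into an interval index
#'
#' Parses GFF3 or GTF (dialect auto-detected from the attribute syntax),
#' keeps gene-level features, attaches a biotype to each, and classifies
#' biotypes as coding or non-coding. GFF 1-based inclusive coordinates are
#' kept in the underlying `GRanges`; accessors expose 0-based half-open
#' coordinates matching the read records.
#'
#' @param path Path to a GFF3 or GTF file.
#' @param biotypes List with elements `coding` and `noncoding` (character
#'   vectors); see [default_biotypes()].
#' @param unknown_to_noncoding Biotypes in neither set are classified
#'   non-coding with a warning when `TRUE` (default); when `FALSE`, reads
#'   overlapping only unknown-biotype features become `ambiguous`.
#' @param gene_types GFF/GTF `type` values treated as gene-level features.
#' @return An object of class `annotation_index`: a list with the feature
#'   `GRanges` (`features`, metadata columns `feature_id`, `gene_id`,
#'   `biotype`, `coding`) and the classification sets.
#' @export
load_annotation <- function(path, biotypes = default_biotypes(),
                            unknown_to_noncoding = TRUE,
                            gene_types = c("gene", "ncRNA_gene",
                                           "pseudogene", "rRNA_gene",
                                           "tRNA_gene", "snoRNA_gene",
                                           "snRNA_gene")) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (length(intersect(biotypes$coding, biotypes$noncoding)) > 0L) {
    stop("coding and noncoding biotype sets must be disjoint")
  }
  fmt <- detect_annotation_dialect(path)
  gr <- tryCatch(rtracklayer::import(path, format = fmt),
                 error = function(e) stop("failed to parse ", path, ": ",
                                          conditionMessage(e)))
  if (length(gr) == 0L) stop("annotation contains no features: ", path)
  mc <- S4Vectors::mcols(gr)
  keep <- if ("type" %in% names(mc)) as.character(mc$type) %in% gene_types
          else rep(TRUE, length(gr))
  if (!any(keep)) keep <- rep(TRUE, length(gr))  # no gene rows: index all
  gr <- gr[keep]
  mc <- S4Vectors::mcols(gr)

  pick <- function(cols) {
    out <- rep(NA_character_, length(gr))
    for (cl in cols) {
      if (cl %in% names(mc)) {
        v <- as.character(mc[[cl]])
        out[is.na(out) & !is.na(v)] <- v[is.na(out) & !is.na(v)]
      }
    }
    out
  }
  biotype <- pick(c("gene_biotype", "biotype", "transcript_biotype",
                    "gene_type"))
  # fall back to the feature type column when no biotype attribute exists
  fallback <- is.na(biotype) | !nzchar(biotype)
  if ("type" %in% names(mc)) {
    biotype[fallback] <- as.character(mc$type)[fallback]
  } else {
    biotype[fallback] <- "unknown"
  }
  gene_id <- pick(c("gene_id", "ID", "Name"))
  gene_id[is.na(gene_id)] <- paste0("feature_", which(is.na(gene_id)))
  feature_id <- pick(c("ID", "gene_id", "Name"))
  feature_id[is.na(feature_id)] <- gene_id[is.na(feature_id)]

  coding <- biotype %in% biotypes$coding
  known <- coding | biotype %in% biotypes$noncoding
  if (any(!known)) {
    if (unknown_to_noncoding) {
      warning("biotype(s) not in configured sets classified non-coding: ",
              paste(unique(biotype[!known]), collapse = ", "))
    }
  }
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    feature_id = feature_id, gene_id = gene_id,
    biotype = biotype, coding = coding, known_biotype = known
  )
  structure(list(features = gr, biotypes = biotypes,
                 unknown_to_noncoding = unknown_to_noncoding),
            class = "annotation_index")
}

detect_annotation_dialect <- function(path) {
  lines <- readLines(path, n = 200L)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) stop("annotation contains no feature lines: ", path)
  attrs <- vapply(strsplit(body, "\t", fixed = TRUE), function(f) {
    if (length(f) >= 9L) f[9L] else ""
  }, character(1))
  # GTF attributes look like: gene_id "x"; GFF3 like: ID=x;Parent=y
  if (any(grepl("\\w+ +\"[^\"]*\"", attrs))) "gtf" else "gff3"
}

#' Assign reads to annotation features and classify them
#'
#' Each read is intersected with the gene-level feature index (overlap of at
#' least one base). A read overlapping any non-coding feature is classified
#' `noncoding`; a read whose overlaps are all coding is `mRNA`; a read with
#' no overlap is `unassigned`. When unknown biotypes are not folded into the
#' non-coding set, reads overlapping only unknown-biotype features are
#' `ambiguous`.
#'
#' @param reads Read `data.frame` from [load_reads()].
#' @param index `annotation_index` from [load_annotation()].
#' @param stranded Require matching strand for overlap (default `FALSE`:
#'   rRNA loci dominate the contaminant pool regardless of annotated strand).
#' @return The input `data.frame` with added columns `category` (one of
#'   `mRNA`, `noncoding`, `unassigned`, `ambiguous`), `biotype` (biotype
#'   driving the call, `NA` when unassigned), `gene_id` (first coding gene
#'   for mRNA reads, first feature otherwise) and `n_features`.
#' @export
classify_reads <- function(reads, index, stranded = FALSE) {
  stopifnot(inherits(index, "annotation_index"))
  n <- nrow(reads)
  out <- reads
  out$category <- rep("unassigned", n)
  out$biotype <- rep(NA_character_, n)
  out$gene_id <- rep(NA_character_, n)
  out$n_features <- integer(n)
  if (n == 0L) return(out)

  feat <- index$features
  known_chroms <- GenomeInfoDb::seqlevels(feat)
  off <- !(reads$chrom %in% known_chroms)
  if (any(off)) {
    warning(sum(off), " read(s) on chromosome(s) absent from the annotation ",
            "left unassigned: ",
            paste(unique(reads$chrom[off]), collapse = ", "))
  }
  on <- which(!off)
  if (length(on) == 0L) return(out)

  q <- GenomicRanges::GRanges(
    seqnames = reads$chrom[on],
    ranges = IRanges::IRanges(start = reads$start[on] + 1L,
                              end = reads$end[on]),
    strand = reads$strand[on],
    seqinfo = GenomeInfoDb::seqinfo(feat)
  )
  hits <- GenomicRanges::findOverlaps(q, feat, ignore.strand = !stranded)
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  mc <- S4Vectors::mcols(feat)
  fold_unknown <- index$unknown_to_noncoding

  if (length(qh) > 0L) {
    sp <- split(sh, qh)
    ridx <- on[as.integer(names(sp))]
    res <- t(vapply(sp, function(ix) {
      bt <- mc$biotype[ix]
      coding <- mc$coding[ix]
      known <- mc$known_biotype[ix]
      noncod <- if (fold_unknown) !coding else (known & !coding)
      if (any(noncod)) {
        c("noncoding", bt[noncod][1L], mc$gene_id[ix][noncod][1L])
      } else if (any(coding)) {
        c("mRNA", bt[coding][1L], mc$gene_id[ix][coding][1L])
      } else {
        c("ambiguous", bt[1L], mc$gene_id[ix][1L])
      }
    }, character(3)))
    out$category[ridx] <- res[, 1L]
    out$biotype[ridx] <- res[, 2L]
    out$gene_id[ridx] <- res[, 3L]
    out$n_features[on[as.integer(names(sp))]] <- lengths(sp)
  }
  out
}

#' Per-sample classification summary
#'
#' @param classes Classified reads from [classify_reads()].
#' @return A `data.frame` with columns `sample_id`, `category`, `read_count`
#'   and `fraction` (of that sample's reads).
#' @export
classification_summary <- function(classes) {
  cats <- c("mRNA", "noncoding", "unassigned", "ambiguous")
  tab <- table(factor(classes$sample_id),
               factor(classes$category, levels = cats))
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df) <- c("sample_id", "category", "read_count")
  tot <- tapply(df$read_count, df$sample_id, sum)
  df$fraction <- df$read_count / as.numeric(tot[df$sample_id])
  df[order(df$sample_id, df$category), , drop = FALSE]
}

#' Write the classification summary to TSV
#'
#' @inheritParams classification_summary
#' @param path Output TSV path.
#' @return Invisibly, the summary `data.frame`.
#' @export
write_classification_summary <- function(classes, path) {
  df <- classification_summary(classes)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
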