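#' Contaminant depletion metrics between two sample arms
#'
#' Compares an undepleted arm with an LNA-depleted arm. The contaminant
#' burden of an arm is the summed per-sample percentage of groups whose
#' dominant classification is non-coding, averaged over the arm's samples.
#' With `shared_patterns = TRUE` (default) the depleted arm is requantified
#' against the undepleted arm's group patterns, so exactly the same targets
#' are compared in both arms.
#'
#' @param undepleted,depleted Lists with elements `result` (an
#'   `aggregation_result`) and `totals` (named per-sample totals).
#' @param shared_patterns Requantify the depleted arm on the undepleted
#'   arm's patterns (default `TRUE`).
#' @param all_noncoding Use every non-coding classified collapsed read as
#'   the contaminant burden instead of only grouped reads (default `FALSE`,
#'   matching the cumulative-groups definition).
#' @return A list with `contaminant_pct_undepleted`,
#'   `contaminant_pct_depleted`, `relative_reduction_pct`
#'   (`100 * (1 - depleted/undepleted)`) and `absolute_reduction_points`.
#' @export
depletion_metrics <- function(undepleted, depleted, shared_patterns = TRUE,
                              all_noncoding = FALSE) {
  dep_result <- depleted$result
  if (shared_patterns) {
    pats <- vapply(undepleted$result$groups, `[[`, character(1), "pattern")
    if (length(pats) > 0L) {
      dep_result <- requantify_groups(pats, depleted$result$collapsed)
    }
  } else {
    up <- vapply(undepleted$result$groups, `[[`, character(1), "pattern")
    dp <- vapply(depleted$result$groups, `[[`, character(1), "pattern")
    if (length(intersect(up, dp)) == 0L) {
      warning("undepleted and depleted arms share no group patterns; ",
              "percentages compare different targets")
    }
  }
  u <- contaminant_pct(undepleted$result, undepleted$totals, all_noncoding)
  d <- contaminant_pct(dep_result, depleted$totals, all_noncoding)
  rel <- if (u > 0) 100 * (1 - d / u) else NA_real_
  list(contaminant_pct_undepleted = u,
       contaminant_pct_depleted = d,
       relative_reduction_pct = rel,
       absolute_reduction_points = u - d)
}

# mean over samples of summed non-coding group percentages
contaminant_pct <- function(result, totals, all_noncoding = FALSE) {
  samples <- colnames(result$collapsed$counts)
  totals <- totals[samples]
  if (all_noncoding) {
    nc <- result$collapsed$category == "noncoding"
    cnt <- colSums(result$collapsed$counts[nc, , drop = FALSE])
    return(mean(100 * cnt / as.numeric(totals)))
  }
  g <- Filter(function(x) identical(x$dominant_category, "noncoding"),
              result$groups)
  if (length(g) == 0L) return(0)
  cnt <- Reduce(`+`, lapply(g, `[[`, "counts"))
  mean(100 * cnt / as.numeric(totals))
}

#' mRNA yield comparison between arms
#'
#' An mRNA read is a read classified `mRNA` whose length is strictly greater
#' than `min_len_exclusive` (default 20 nt, so a 20-nt read is excluded).
#' Percentages are relative to each sample's total filtered reads; the
#' yield ratio is the depleted over the undepleted mean percentage.
#'
#' @param undepleted_classes,depleted_classes Classified read frames from
#'   [classify_reads()].
#' @param min_len_exclusive Exclusive lower length bound (default 20).
#' @return A list with `mrna_pct_undepleted`, `mrna_pct_depleted` and
#'   `mrna_yield_ratio`.
#' @export
mrna_yield <- function(undepleted_classes, depleted_classes,
                       min_len_exclusive = 20L) {
  pct <- function(cl) {
    tot <- sample_totals(cl)
    is_mrna <- cl$category == "mRNA" &
      nchar(cl$sequence) > min_len_exclusive
    m <- table(factor(cl$sample_id[is_mrna], levels = names(tot)))
    mean(100 * as.numeric(m) / tot)
  }
  u <- pct(undepleted_classes)
  if (!is.finite(u) || u == 0) {
    stop("undepleted arm contains no mRNA reads above the length bound")
  }
  d <- pct(depleted_classes)
  list(mrna_pct_undepleted = u, mrna_pct_depleted = d,
       mrna_yield_ratio = d / u)
}

#' Gene-level count table for mRNA reads
#'
#' @param classes Classified reads from [classify_reads()].
#' @param min_len_exclusive Exclusive length bound applied before counting.
#' @return A matrix of read counts, genes x samples.
#' @export
gene_counts <- function(classes, min_len_exclusive = 20L) {
  keep <- classes$category == "mRNA" &
    nchar(classes$sequence) > min_len_exclusive & !is.na(classes$gene_id)
  cl <- classes[keep, , drop = FALSE]
  tab <- table(factor(cl$gene_id), factor(cl$sample_id))
  m <- matrix(as.numeric(tab), nrow = nrow(tab),
              dimnames = dimnames(tab))
  m
}

#' Gene-level count correlation between arms
#'
#' Counts are averaged across replicates within each arm, transformed with
#' `log2(x + 1)` as a variance-stabilising shifted-log, and correlated
#' (Pearson) over genes with a nonzero mean count in at least one arm. A
#' near-1 coefficient indicates that depletion left gene-level
#' quantification intact.
#'
#' @param undepleted_counts,depleted_counts Gene count matrices (genes x
#'   replicate samples) from [gene_counts()]; row names are gene ids and the
#'   union of genes is used (absent genes count 0).
#' @return A list with `r` (Pearson coefficient on transformed means),
#'   `n_genes` and the per-gene table (`genes`: gene_id, mean counts and
#'   transformed values per arm).
#' @export
gene_correlation <- function(undepleted_counts, depleted_counts) {
  genes <- union(rownames(undepleted_counts), rownames(depleted_counts))
  mean_for <- function(m) {
    v <- structure(numeric(length(genes)), names = genes)
    if (length(m) > 0L) {
      v[rownames(m)] <- rowMeans(m)
    }
    v
  }
  u <- mean_for(undepleted_counts)
  d <- mean_for(depleted_counts)
  keep <- u > 0 | d > 0
  u <- u[keep]; d <- d[keep]
  if (length(u) < 3L) {
    stop("fewer than 3 genes with nonzero counts; cannot correlate")
  }
  tu <- log2(u + 1)
  td <- log2(d + 1)
  r <- stats::cor(tu, td, method = "pearson")
  list(r = r, n_genes = length(u),
       genes = data.frame(gene_id = names(u),
                          mean_undepleted = as.numeric(u),
                          mean_depleted = as.numeric(d),
                          log2_undepleted = as.numeric(tu),
                          log2_depleted = as.numeric(td),
                          stringsAsFactors = FALSE))
}

#' qPCR target abundance from a cycle-threshold difference
#'
#' Converts a qPCR cycle difference into a relative target abundance:
#' `100 * efficiency^(ct_control - ct_treated)` percent of the undepleted
#' control. At perfect efficiency (2), each extra cycle in the treated
#' sample halves the apparent abundance; a cycle difference of 10
#' corresponds to a more than 1000-fold reduction.
#'
#' @param ct_treated Cycle threshold of the LNA-treated reaction.
#' @param ct_control Cycle threshold of the untreated control.
#' @param efficiency Amplification efficiency per cycle, in (1, 2]
#'   (default 2, perfect doubling).
#' @return Abundance as a percentage of the control.
#' @export
qpcr_abundance <- function(ct_treated, ct_control, efficiency = 2) {
  stopifnot(efficiency > 1, efficiency <= 2)
  100 * efficiency^(ct_control - ct_treated)
}

#' Full depletion report between two arms
#'
#' Convenience wrapper combining [depletion_metrics()], [mrna_yield()] and
#' [gene_correlation()] into one record.
#'
#' @param undepleted_classes,depleted_classes Classified read frames, one
#'   per arm.
#' @param n_patterns,scope Passed to [select_patterns()].
#' @param shared_patterns,all_noncoding Passed to [depletion_metrics()].
#' @param min_len_exclusive Passed to [mrna_yield()] and [gene_counts()].
#' @return An object of class `depletion_report`: a list with the fields of
#'   the three component records plus `n_genes`.
#' @export
depletion_report <- function(undepleted_classes, depleted_classes,
                             n_patterns = 10000L, scope = "all",
                             shared_patterns = TRUE, all_noncoding = FALSE,
                             min_len_exclusive = 20L) {
  arm <- function(cl) {
    collapsed <- collapse_reads(cl)
    pats <- select_patterns(collapsed, n_patterns = n_patterns, scope = scope)
    list(result = aggregate_groups(pats, collapsed),
         totals = sample_totals(cl))
  }
  u <- arm(undepleted_classes)
  d <- arm(depleted_classes)
  dm <- depletion_metrics(u, d, shared_patterns = shared_patterns,
                          all_noncoding = all_noncoding)
  my <- mrna_yield(undepleted_classes, depleted_classes,
                   min_len_exclusive = min_len_exclusive)
  gc <- gene_correlation(gene_counts(undepleted_classes, min_len_exclusive),
                         gene_counts(depleted_classes, min_len_exclusive))
  structure(c(dm, my,
              list(gene_correlation = gc$r, n_genes = gc$n_genes,
                   gene_table = gc$genes,
                   undepleted = u, depleted = d)),
            class = "depletion_report")
}

#' @export
print.depletion_report <- function(x, ...) {
  cat(sprintf(paste0(
    "depletion_report:\n",
    "  contaminants: %.2f%% -> %.2f%% (relative reduction %.1f%%, ",
    "%.1f points)\n",
    "  mRNA yield:   %.2f%% -> %.2f%% (ratio %.2f)\n",
    "  gene-level Pearson r = %.4f over %d genes\n"),
    x$contaminant_pct_undepleted, x$contaminant_pct_depleted,
    x$relative_reduction_pct, x$absolute_reduction_points,
    x$mrna_pct_undepleted, x$mrna_pct_depleted, x$mrna_yield_ratio,
    x$gene_correlation, x$n_genes))
  invisible(x)
}

#' Write a depletion report to disk
#'
#' Writes `depletion_report.json` (scalar metrics plus method metadata) and
#' `gene_correlation.tsv` (per-gene mean and transformed counts).
#'
#' @param report A `depletion_report`.
#' @param outdir Output directory (created if absent).
#' @return Invisibly, the files written.
#' @export
write_depletion_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scalars <- report[c("contaminant_pct_undepleted", "contaminant_pct_depleted",
                      "relative_reduction_pct", "absolute_reduction_points",
                      "mrna_pct_undepleted", "mrna_pct_depleted",
                      "mrna_yield_ratio", "gene_correlation", "n_genes")]
  scalars$count_transform <- "log2(count + 1) on replicate-averaged counts"
  jp <- file.path(outdir, "depletion_report.json")
  jsonlite::write_json(scalars, jp, auto_unbox = TRUE, digits = NA)
  tp <- file.path(outdir, "gene_correlation.tsv")
  utils::write.table(report$gene_table, tp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(jp, tp))
}
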