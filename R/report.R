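#' Per-sample totals of filtered reads
#'
#' @param reads Read (or classified-read) `data.frame`.
#' @return Named numeric vector: reads per sample after the length filter.
#' @export
sample_totals <- function(reads) {
  tab <- table(reads$sample_id)
  structure(as.numeric(tab), names = names(tab))
}

#' Contaminant percentage matrix (heatmap table)
#'
#' One row per top-ranked group, one column per sample; each value is the
#' percentage of the sample's total filtered reads captured by that group.
#' Cumulative percentages over the displayed rows are attached per column,
#' mirroring the column summaries of a contaminant heatmap.
#'
#' @param result An `aggregation_result`.
#' @param totals Named vector of per-sample total filtered reads (see
#'   [sample_totals()]); must be positive for every sample.
#' @param top_k Number of groups to display (default 10). When fewer groups
#'   exist, all are shown.
#' @return An object of class `percent_matrix`: list with `values` (matrix,
#'   rows = group patterns, cols = samples), `column_cumulative`, `ranks`
#'   and `dominant_biotype`.
#' @export
percent_matrix <- function(result, totals, top_k = 10L) {
  samples <- colnames(result$collapsed$counts)
  totals <- totals[samples]
  if (any(is.na(totals)) || any(totals <= 0)) {
    stop("totals must be positive for every sample in the result")
  }
  g <- result$groups
  k <- min(top_k, length(g))
  if (k == 0L) stop("aggregation result contains no groups")
  g <- g[seq_len(k)]  # groups are stored rank-ordered
  vals <- do.call(rbind, lapply(g, function(x) {
    100 * x$counts / as.numeric(totals)
  }))
  dimnames(vals) <- list(vapply(g, `[[`, character(1), "pattern"), samples)
  structure(list(values = vals,
                 column_cumulative = colSums(vals),
                 ranks = vapply(g, `[[`, integer(1), "rank"),
                 dominant_biotype = vapply(g, `[[`, character(1),
                                           "dominant_biotype")),
            class = "percent_matrix")
}

#' Figure of merit: cumulative targeted percentage vs blocker set size
#'
#' For each candidate LNA set size k, the expected depletion payoff is the
#' cumulative percentage of library reads captured by the k most abundant
#' groups. Per-sample curves and their mean are returned; the curve is
#' non-decreasing and its terminal value equals the total grouped
#' percentage.
#'
#' @inheritParams percent_matrix
#' @return An object of class `figure_of_merit`: list with `set_size`,
#'   `cumulative_pct` (mean over samples) and `per_sample_curves` (matrix,
#'   rows = set sizes, cols = samples).
#' @export
figure_of_merit <- function(result, totals) {
  samples <- colnames(result$collapsed$counts)
  totals <- totals[samples]
  g <- result$groups
  if (length(g) == 0L) stop("aggregation result contains no groups")
  pct <- do.call(rbind, lapply(g, function(x) {
    100 * x$counts / as.numeric(totals)
  }))
  curves <- apply(pct, 2L, cumsum)
  if (length(g) == 1L) curves <- matrix(curves, nrow = 1L)
  dimnames(curves) <- list(NULL, samples)
  structure(list(set_size = seq_along(g),
                 cumulative_pct = rowMeans(curves),
                 per_sample_curves = curves),
            class = "figure_of_merit")
}

#' @export
print.percent_matrix <- function(x, ...) {
  cat("percent_matrix:", nrow(x$values), "groups x", ncol(x$values),
      "samples; cumulative:",
      paste(sprintf("%s=%.2f%%", colnames(x$values), x$column_cumulative),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.figure_of_merit <- function(x, ...) {
  n <- length(x$set_size)
  cat("figure_of_merit:", n, "set sizes; mean cumulative at k=", n, ":",
      sprintf("%.2f%%", x$cumulative_pct[n]), "\n")
  invisible(x)
}

#' Export heatmap table and figure-of-merit curve
#'
#' Writes `heatmap.tsv` (group pattern rows, per-sample percentage columns,
#' with rank and biotype, plus a trailing cumulative row) and
#' `figure_of_merit.tsv` (set size, mean cumulative percentage, per-sample
#' curves). With `plot = TRUE` also writes `heatmap.png` and
#' `figure_of_merit.png`. All percentages are written with 4 decimals.
#'
#' @param matrix_obj A `percent_matrix`.
#' @param fom A `figure_of_merit`.
#' @param outdir Output directory (created if absent).
#' @param plot Also write PNG figures (default `FALSE`).
#' @return Invisibly, the vector of files written.
#' @export
export_reports <- function(matrix_obj, fom, outdir, plot = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  vals <- round(matrix_obj$values, 4)
  hm <- data.frame(rank = matrix_obj$ranks,
                   pattern = rownames(matrix_obj$values),
                   dominant_biotype = matrix_obj$dominant_biotype,
                   stringsAsFactors = FALSE)
  hm <- cbind(hm, as.data.frame(vals, row.names = NULL))
  cum <- data.frame(rank = NA_integer_, pattern = "cumulative",
                    dominant_biotype = NA_character_,
                    stringsAsFactors = FALSE)
  cum <- cbind(cum, as.data.frame(t(round(matrix_obj$column_cumulative, 4))))
  names(cum) <- names(hm)
  hm_path <- file.path(outdir, "heatmap.tsv")
  utils::write.table(rbind(hm, cum), hm_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, hm_path)

  fdf <- data.frame(set_size = fom$set_size,
                    mean_cumulative_pct = round(fom$cumulative_pct, 4))
  fdf <- cbind(fdf, as.data.frame(round(fom$per_sample_curves, 4)))
  fom_path <- file.path(outdir, "figure_of_merit.tsv")
  utils::write.table(fdf, fom_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  files <- c(files, fom_path)

  if (plot) {
    hm_png <- file.path(outdir, "heatmap.png")
    grDevices::png(hm_png, width = 900, height = 600)
    v <- matrix_obj$values
    graphics::image(x = seq_len(ncol(v)), y = seq_len(nrow(v)),
                    z = t(v[rev(seq_len(nrow(v))), , drop = FALSE]),
                    col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                    axes = FALSE, xlab = "", ylab = "",
                    main = "Contaminant group percentage per sample")
    graphics::axis(1, at = seq_len(ncol(v)), labels = colnames(v), las = 2)
    graphics::axis(2, at = seq_len(nrow(v)), labels = rev(rownames(v)),
                   las = 1, cex.axis = 0.6)
    grDevices::dev.off()
    files <- c(files, hm_png)

    fom_png <- file.path(outdir, "figure_of_merit.png")
    grDevices::png(fom_png, width = 700, height = 500)
    graphics::plot(fom$set_size, fom$cumulative_pct, type = "b", pch = 19,
                   xlab = "LNA set size",
                   ylab = "Cumulative targeted reads (%)",
                   main = "Figure of merit")
    grDevices::dev.off()
    files <- c(files, fom_png)
  }
  invisible(files)
}
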