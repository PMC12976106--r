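#' Assemble the effective run configuration
#'
#' Collects all tunable pipeline parameters with their defaults; values in
#' `overrides` (a named list, e.g. parsed from a flat key-value config file)
#' replace defaults. The effective configuration is serialised into every
#' output directory as a reproducibility record.
#'
#' @param overrides Named list of parameter overrides.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(min_len = 20L, max_len = 30L, n_patterns = 10000L,
              scope = "all", top_k = 10L, probe_min = 14L, probe_max = 20L,
              n_probes = 5L, orientation = "antisense", stranded = FALSE,
              min_len_exclusive = 20L, shared_patterns = TRUE,
              all_noncoding = FALSE, seed = 1L, plot = FALSE)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Read a flat key-value configuration file
#'
#' Lines of the form `key: value` or `key = value`; `#` starts a comment.
#' Values are coerced to numeric/logical where possible.
#'
#' @param path Config file path.
#' @return Named list suitable for [run_config()].
#' @export
read_config_file <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(.*)$",
                                ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    val <- trimws(m[3])
    if (grepl("^(true|false)$", tolower(val))) {
      val <- as.logical(toupper(val))
    } else if (grepl("^-?[0-9.]+$", val)) {
      val <- as.numeric(val)
      if (val == round(val)) val <- as.integer(val)
    }
    out[[m[2]]] <- val
  }
  out
}

write_config <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  scalars <- cfg[vapply(cfg, function(x) is.atomic(x) && length(x) == 1L,
                        logical(1))]
  writeLines(paste0(names(scalars), ": ",
                    vapply(scalars, as.character, character(1))),
             file.path(outdir, "run_config.txt"))
}

#' Identify contaminants end to end
#'
#' Runs the full identification pipeline: load and length-filter reads for
#' every manifest sample, classify against the annotation, collapse to
#' unique sequences, select abundance-ranked patterns, group by greedy
#' substring containment, and export the group table, heatmap table and
#' figure-of-merit curve.
#'
#' @param manifest Path to a sample manifest, or a `sample_manifest`.
#' @param annotation Path to GFF3/GTF, or an `annotation_index`.
#' @param outdir Output directory.
#' @param config A `run_config` (or named list of overrides).
#' @return Invisibly, a list with `result` (`aggregation_result`),
#'   `classes`, `totals`, `matrix`, `fom` and output file paths.
#' @export
run_identify <- function(manifest, annotation, outdir,
                         config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  reads <- load_manifest_reads(manifest, min_len = config$min_len,
                               max_len = config$max_len)
  if (nrow(reads) == 0L) stop("no reads passed the length filter")
  classes <- classify_reads(reads, annotation, stranded = config$stranded)
  collapsed <- collapse_reads(classes, samples = manifest$sample_id)
  patterns <- select_patterns(collapsed, n_patterns = config$n_patterns,
                              scope = config$scope)
  result <- aggregate_groups(patterns, collapsed)
  totals <- sample_totals(classes)
  m <- percent_matrix(result, totals, top_k = config$top_k)
  fom <- figure_of_merit(result, totals)

  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  gt <- groups_table(result, totals)
  gpath <- file.path(outdir, "groups.tsv")
  utils::write.table(gt, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- export_reports(m, fom, outdir, plot = isTRUE(config$plot))
  write_classification_summary(classes,
                               file.path(outdir, "classification.tsv"))
  write_config(config, outdir)
  invisible(list(result = result, classes = classes, totals = totals,
                 matrix = m, fom = fom,
                 files = c(groups = gpath, files)))
}

#' Design probes from an identification run
#'
#' @param groups A groups table (path to `groups.tsv` or `data.frame`) or an
#'   `aggregation_result`.
#' @param outdir Output directory for the order sheet.
#' @param config A `run_config` (or overrides): `n_probes`, `probe_min`,
#'   `probe_max`, `orientation`.
#' @return Invisibly, the result of [design_probe_set()] plus the order
#'   sheet path.
#' @export
run_design <- function(groups, outdir, config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.character(groups)) {
    groups <- utils::read.table(groups, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  }
  ps <- design_probe_set(groups, n_probes = config$n_probes,
                         min_len = config$probe_min,
                         max_len = config$probe_max,
                         orientation = config$orientation)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sheet <- file.path(outdir, "order_sheet.tsv")
  write_order_sheet(ps, sheet)
  if (nrow(ps$skipped) > 0L) {
    utils::write.table(ps$skipped, file.path(outdir, "skipped_groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_config(config, outdir)
  invisible(c(ps, list(order_sheet = sheet)))
}

#' Evaluate depletion performance from a two-arm manifest
#'
#' Splits the manifest on its `depleted` flag, runs classification on both
#' arms and computes the full depletion report.
#'
#' @param manifest Path to a manifest containing both arms, or a
#'   `sample_manifest`.
#' @param annotation Path to GFF3/GTF, or an `annotation_index`.
#' @param outdir Output directory.
#' @param config A `run_config` (or overrides).
#' @return Invisibly, the `depletion_report`.
#' @export
run_evaluate <- function(manifest, annotation, outdir,
                         config = run_config()) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  if (is.character(manifest)) manifest <- load_manifest(manifest)
  if (is.character(annotation)) annotation <- load_annotation(annotation)
  if (!any(manifest$depleted) || all(manifest$depleted)) {
    stop("manifest must contain both undepleted and depleted samples")
  }
  arm_classes <- function(m) {
    reads <- load_manifest_reads(m, min_len = config$min_len,
                                 max_len = config$max_len)
    classify_reads(reads, annotation, stranded = config$stranded)
  }
  u <- arm_classes(manifest[!manifest$depleted, , drop = FALSE])
  d <- arm_classes(manifest[manifest$depleted, , drop = FALSE])
  rep <- depletion_report(u, d,
                          n_patterns = config$n_patterns,
                          scope = config$scope,
                          shared_patterns = config$shared_patterns,
                          all_noncoding = config$all_noncoding,
                          min_len_exclusive = config$min_len_exclusive)
  write_depletion_report(rep, outdir)
  write_config(config, outdir)
  invisible(rep)
}
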