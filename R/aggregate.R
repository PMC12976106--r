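#' Collapse identical reads into counted unique sequences
#'
#' Identical read sequences are collapsed to one record carrying per-sample
#' occurrence counts. The classification category and biotype of a collapsed
#' read are decided by majority vote over its constituent reads (identical
#' sequences originate from one locus and share a class); category ties are
#' resolved towards `noncoding`, biotype ties lexicographically.
#'
#' @param classes Classified reads from [classify_reads()] (unclassified read
#'   frames are accepted: category defaults to `unassigned`).
#' @param samples Sample ids defining the count columns; defaults to the
#'   samples present, in order of first appearance.
#' @return An object of class `collapsed_reads`: a list with `sequence`
#'   (character), `counts` (integer matrix, one column per sample), `total`
#'   (row sums), `category` and `biotype`.
#' @export
collapse_reads <- function(classes, samples = NULL) {
  if (is.null(classes$category)) classes$category <- "unassigned"
  if (is.null(classes$biotype)) classes$biotype <- NA_character_
  if (is.null(samples)) samples <- unique(classes$sample_id)
  n <- nrow(classes)
  if (n == 0L) {
    return(new_collapsed(character(0),
                         matrix(0L, 0L, length(samples),
                                dimnames = list(NULL, samples)),
                         character(0), character(0)))
  }
  useq <- sort(unique(classes$sequence))
  si <- match(classes$sequence, useq)
  sj <- match(classes$sample_id, samples)
  if (anyNA(sj)) stop("reads carry sample_id values absent from 'samples'")
  counts <- matrix(0L, nrow = length(useq), ncol = length(samples),
                   dimnames = list(NULL, samples))
  tab <- table(si, sj)
  counts[cbind(as.integer(rownames(tab))[row(tab)],
               as.integer(colnames(tab))[col(tab)])] <- as.integer(tab)

  category <- unname(vapply(
    split(classes$category, si)[as.character(seq_along(useq))],
    majority_category, character(1)))
  biotype <- unname(vapply(
    split(classes$biotype, si)[as.character(seq_along(useq))],
    majority_label, character(1)))
  new_collapsed(useq, counts, category, biotype)
}

new_collapsed <- function(sequence, counts, category, biotype) {
  structure(list(sequence = sequence, counts = counts,
                 total = as.numeric(rowSums(counts)),
                 category = category, biotype = biotype),
            class = "collapsed_reads")
}

majority_category <- function(x) {
  tab <- table(x)
  top <- names(tab)[tab == max(tab)]
  if ("noncoding" %in% top) "noncoding" else sort(top)[1L]
}

majority_label <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_character_)
  tab <- table(x)
  sort(names(tab)[tab == max(tab)])[1L]
}

#' @export
length.collapsed_reads <- function(x) length(x$sequence)

#' Subset collapsed reads
#'
#' @param x A `collapsed_reads` object.
#' @param i Index vector.
#' @param ... Ignored.
#' @export
`[.collapsed_reads` <- function(x, i, ...) {
  new_collapsed(x$sequence[i], x$counts[i, , drop = FALSE],
                x$category[i], x$biotype[i])
}

#' @export
as.data.frame.collapsed_reads <- function(x, ...) {
  df <- data.frame(sequence = x$sequence, total = x$total,
                   category = x$category, biotype = x$biotype,
                   stringsAsFactors = FALSE)
  cbind(df, as.data.frame(x$counts))
}

#' @export
print.collapsed_reads <- function(x, ...) {
  cat("collapsed_reads:", length(x), "unique sequences,",
      sum(x$total), "reads,", ncol(x$counts), "sample(s)\n")
  invisible(x)
}

#' Select abundance-ranked matching patterns
#'
#' Returns the `n_patterns` most abundant collapsed reads (by cross-sample
#' total) to serve as matching patterns for the greedy grouping. Ties on
#' abundance are broken lexicographically by sequence so selection is
#' deterministic.
#'
#' @param collapsed A `collapsed_reads` object.
#' @param n_patterns Number of patterns to select (default 10000). When fewer
#'   collapsed reads exist, all are returned.
#' @param scope `"all"` (default) selects patterns from every collapsed read;
#'   `"noncoding"` restricts selection to reads classified non-coding.
#' @return A `collapsed_reads` object ordered by descending total.
#' @export
select_patterns <- function(collapsed, n_patterns = 10000L,
                            scope = c("all", "noncoding")) {
  stopifnot(n_patterns >= 1L)
  scope <- match.arg(scope)
  idx <- seq_along(collapsed$sequence)
  if (scope == "noncoding") idx <- idx[collapsed$category == "noncoding"]
  ord <- idx[order(-collapsed$total[idx], collapsed$sequence[idx])]
  collapsed[ord[seq_len(min(n_patterns, length(ord)))]]
}

#' Greedy substring-containment grouping with elimination
#'
#' The core contaminant-identification algorithm. Patterns are processed in
#' ascending length order (ties: descending abundance, then lexicographic).
#' For each pattern still present in the search set, every remaining search
#' sequence containing the pattern as an exact contiguous substring (sense
#' strand only) joins the pattern's group; group counts are the sums over
#' members, and the shortest common sequence of the group is the pattern
#' itself. All matched sequences — including the pattern — are then
#' eliminated from the search set before the next pattern is queued, so each
#' collapsed read belongs to at most one group. Groups are finally re-ranked
#' by descending total for reporting.
#'
#' @param patterns `collapsed_reads` of matching patterns, typically from
#'   [select_patterns()]. Every pattern sequence must be present in
#'   `search_set`.
#' @param search_set `collapsed_reads` to group (usually all collapsed reads).
#' @return An object of class `aggregation_result`: list with `groups` (list
#'   of groups: `pattern`, `member_idx` into `search_set`, `counts` named
#'   vector, `total`, `n_members`, `dominant_biotype`, `dominant_category`),
#'   `ungrouped` (indices), `collapsed` (the search set) and `params`.
#' @export
aggregate_groups <- function(patterns, search_set) {
  seqs <- search_set$sequence
  pat <- patterns$sequence
  if (!all(pat %in% seqs)) {
    stop("every pattern sequence must be present in the search set")
  }
  ord <- order(nchar(pat), -patterns$total, pat)
  pat <- pat[ord]
  pat <- pat[!duplicated(pat)]

  alive <- rep(TRUE, length(seqs))
  groups <- list()
  for (p in pat) {
    self <- match(p, seqs)
    if (!alive[self]) next  # consumed by an earlier (shorter) pattern
    hit <- alive & grepl(p, seqs, fixed = TRUE)
    idx <- which(hit)
    groups[[length(groups) + 1L]] <- make_group(p, idx, search_set)
    alive[hit] <- FALSE
  }
  if (length(groups) > 0L) {
    totals <- vapply(groups, `[[`, numeric(1), "total")
    pats <- vapply(groups, `[[`, character(1), "pattern")
    groups <- groups[order(-totals, pats)]
    for (i in seq_along(groups)) groups[[i]]$rank <- i
  }
  structure(list(groups = groups, ungrouped = which(alive),
                 collapsed = search_set,
                 params = list(n_patterns = length(pat),
                               scope = "as-supplied",
                               tie_break = "length, -total, lexicographic")),
            class = "aggregation_result")
}

make_group <- function(pattern, idx, collapsed) {
  cnt <- collapsed$counts[idx, , drop = FALSE]
  counts <- colSums(cnt)
  w <- collapsed$total[idx]
  list(pattern = pattern, member_idx = idx, counts = counts,
       total = sum(counts), n_members = length(idx),
       dominant_biotype = weighted_majority(collapsed$biotype[idx], w),
       dominant_category = weighted_majority(collapsed$category[idx], w,
                                             prefer = "noncoding"),
       rank = NA_integer_)
}

weighted_majority <- function(labels, w, prefer = NULL) {
  keep <- !is.na(labels)
  if (!any(keep)) return(NA_character_)
  tot <- tapply(w[keep], labels[keep], sum)
  top <- names(tot)[tot == max(tot)]
  if (!is.null(prefer) && prefer %in% top) return(prefer)
  sort(top)[1L]
}

#' @export
print.aggregation_result <- function(x, ...) {
  cat("aggregation_result:", length(x$groups), "groups,",
      length(x$ungrouped), "ungrouped sequences\n")
  invisible(x)
}

#' Tabulate an aggregation result
#'
#' @param result An `aggregation_result`.
#' @param totals Optional named vector of per-sample total filtered reads;
#'   when supplied, per-sample percentage columns (`pct.*`) are added.
#' @return A `data.frame` with one row per group: `rank`, `pattern`,
#'   `length`, `dominant_biotype`, `dominant_category`, `n_members`, `total`
#'   and per-sample count columns (`count.*`).
#' @export
groups_table <- function(result, totals = NULL) {
  g <- result$groups
  samples <- colnames(result$collapsed$counts)
  if (length(g) == 0L) {
    df <- data.frame(rank = integer(0), pattern = character(0),
                     length = integer(0), dominant_biotype = character(0),
                     dominant_category = character(0),
                     n_members = integer(0), total = numeric(0))
    for (s in samples) df[[paste0("count.", s)]] <- numeric(0)
    return(df)
  }
  cnt <- do.call(rbind, lapply(g, `[[`, "counts"))
  colnames(cnt) <- paste0("count.", samples)
  df <- data.frame(
    rank = vapply(g, `[[`, integer(1), "rank"),
    pattern = vapply(g, `[[`, character(1), "pattern"),
    length = nchar(vapply(g, `[[`, character(1), "pattern")),
    dominant_biotype = vapply(g, `[[`, character(1), "dominant_biotype"),
    dominant_category = vapply(g, `[[`, character(1), "dominant_category"),
    n_members = vapply(g, `[[`, integer(1), "n_members"),
    total = vapply(g, `[[`, numeric(1), "total"),
    stringsAsFactors = FALSE
  )
  df <- cbind(df, as.data.frame(cnt))
  if (!is.null(totals)) {
    for (s in samples) {
      df[[paste0("pct.", s)]] <- 100 * cnt[, paste0("count.", s)] /
        as.numeric(totals[[s]])
    }
  }
  rownames(df) <- NULL
  df
}

#' Requantify a fixed pattern set against another read collection
#'
#' Applies the greedy containment grouping with a fixed, externally supplied
#' pattern list (e.g. the patterns discovered in an undepleted arm) to a new
#' collapsed-read set, so the same targets can be compared across arms.
#' Unlike [aggregate_groups()], patterns need not be members of the search
#' set and groups may be empty.
#'
#' @param pattern_seqs Character vector of pattern sequences.
#' @param collapsed `collapsed_reads` to quantify against.
#' @return An `aggregation_result`; group order follows `pattern_seqs`
#'   processing order re-ranked by total, empty groups retained.
#' @export
requantify_groups <- function(pattern_seqs, collapsed) {
  seqs <- collapsed$sequence
  pat <- unique(pattern_seqs[order(nchar(pattern_seqs), pattern_seqs)])
  alive <- rep(TRUE, length(seqs))
  groups <- list()
  for (p in pat) {
    hit <- alive & grepl(p, seqs, fixed = TRUE)
    idx <- which(hit)
    g <- make_group(p, idx, collapsed)
    if (g$n_members == 0L) {
      g$counts <- structure(numeric(ncol(collapsed$counts)),
                            names = colnames(collapsed$counts))
      g$total <- 0
    }
    groups[[length(groups) + 1L]] <- g
    alive[hit] <- FALSE
  }
  totals <- vapply(groups, `[[`, numeric(1), "total")
  pats <- vapply(groups, `[[`, character(1), "pattern")
  groups <- groups[order(-totals, pats)]
  for (i in seq_along(groups)) groups[[i]]$rank <- i
  structure(list(groups = groups, ungrouped = which(alive),
                 collapsed = collapsed,
                 params = list(n_patterns = length(pat),
                               scope = "requantified",
                               tie_break = "length, lexicographic")),
            class = "aggregation_result")
}
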