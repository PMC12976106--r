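test_that("collapsing counts identical sequences per sample", {
  cl <- make_classes(rep("ACGTACGTACGTACGTACGTA", 5),
                     sample_id = c("A", "A", "A", "B", "B"),
                     category = "noncoding", biotype = "rRNA")
  co <- collapse_reads(cl)
  expect_equal(length(co), 1L)
  expect_equal(co$counts[1, ], c(A = 3L, B = 2L))
  expect_equal(co$total, 5)

  cl2 <- make_classes(c("AAAACCCC", "GGGGTTTT"))
  expect_equal(length(collapse_reads(cl2)), 2L)

  expect_equal(length(collapse_reads(make_classes(character(0)))), 0L)
})

test_that("collapsed totals match a hash-count oracle on random input", {
  set.seed(303)
  pool <- replicate(400, random_target(sample(20:30, 1L)))
  seqs <- sample(pool, 10000L, replace = TRUE)
  cl <- make_classes(seqs, sample_id = sample(c("s1", "s2"), 10000L,
                                              replace = TRUE))
  co <- collapse_reads(cl)
  expect_equal(sum(co$total), 10000)
  oracle <- table(seqs)  # independent count
  expect_equal(co$total[match(names(oracle), co$sequence)],
               unname(as.numeric(oracle)))
  expect_equal(unname(colSums(co$counts)),
               unname(as.numeric(table(cl$sample_id))))
})

test_that("category majority vote breaks ties towards noncoding", {
  cl <- make_classes(rep("ACGTACGT", 4),
                     category = c("mRNA", "mRNA", "noncoding", "noncoding"),
                     biotype = c("protein_coding", "protein_coding",
                                 "rRNA", "rRNA"))
  expect_equal(collapse_reads(cl)$category, "noncoding")

  cl2 <- make_classes(rep("ACGTACGT", 3),
                      category = c("mRNA", "mRNA", "noncoding"))
  expect_equal(collapse_reads(cl2)$category, "mRNA")
})

test_that("pattern selection ranks by abundance with lexicographic ties", {
  co <- make_collapsed(list(s1 = c(AAAA = 5L, CCCC = 9L, GGGG = 2L,
                                   TTTT = 9L, ACGT = 1L)))
  top3 <- select_patterns(co, n_patterns = 3L)
  expect_equal(top3$sequence, c("CCCC", "TTTT", "AAAA"))

  all_of_them <- select_patterns(co, n_patterns = 10000L)
  expect_equal(length(all_of_them), 5L)  # saturation: fewer reads than cap

  co2 <- make_collapsed(list(s1 = c(GGGG = 3L, AAAA = 3L)))
  expect_equal(select_patterns(co2, 2L)$sequence, c("AAAA", "GGGG"))
})

test_that("pattern scope can be restricted to noncoding reads", {
  co <- make_collapsed(list(s1 = c(AAAA = 9L, CCCC = 5L)),
                       category = c("mRNA", "noncoding"),
                       biotype = c("protein_coding", "rRNA"))
  expect_equal(select_patterns(co, 5L, scope = "noncoding")$sequence, "CCCC")
  expect_equal(select_patterns(co, 5L, scope = "all")$sequence,
               c("AAAA", "CCCC"))
})

test_that("grouping matches containment by inspection", {
  co <- make_collapsed(list(s1 = c(ACGT = 5L, TACGTG = 3L, GGGG = 2L)))
  pats <- co[co$sequence == "ACGT"]
  res <- aggregate_groups(pats, co)
  expect_equal(length(res$groups), 1L)
  expect_equal(res$groups[[1]]$pattern, "ACGT")
  expect_equal(res$groups[[1]]$total, 8)
  expect_equal(co$sequence[res$ungrouped], "GGGG")
})

test_that("matched reads are eliminated before longer patterns are queued", {
  co <- make_collapsed(list(s1 = c(ACGT = 5L, TACGTG = 3L, GGGG = 2L)))
  pats <- co[co$sequence %in% c("ACGT", "TACGTG")]
  res <- aggregate_groups(pats, co)
  # TACGTG contains ACGT, is consumed by its group, never forms its own
  expect_equal(vapply(res$groups, `[[`, character(1), "pattern"), "ACGT")
  expect_equal(res$groups[[1]]$n_members, 2L)
})

test_that("empty pattern set leaves everything ungrouped", {
  co <- make_collapsed(list(s1 = c(ACGT = 5L, GGGG = 2L)))
  res <- aggregate_groups(co[integer(0)], co)
  expect_equal(length(res$groups), 0L)
  expect_equal(length(res$ungrouped), 2L)
})

test_that("grouping equals the brute-force reference on random inputs", {
  for (seed in c(101, 202, 303)) {
    co <- random_collapsed(seed, n = 300L)
    pats <- select_patterns(co, n_patterns = 50L)
    got <- canonical_result(aggregate_groups(pats, co))
    want <- naive_aggregate(pats, co)
    expect_equal(got, want, info = paste("seed", seed))
  }
})

test_that("disjoint cover, conservation and minimality hold", {
  for (seed in c(7, 77)) {
    co <- random_collapsed(seed, n = 250L)
    pats <- select_patterns(co, n_patterns = 40L)
    res <- aggregate_groups(pats, co)
    member_idx <- unlist(lapply(res$groups, `[[`, "member_idx"))
    expect_equal(sort(c(member_idx, res$ungrouped)), seq_along(co$sequence))
    grouped_total <- sum(vapply(res$groups, `[[`, numeric(1), "total"))
    expect_equal(grouped_total + sum(co$total[res$ungrouped]),
                 sum(co$total))
    for (g in res$groups) {
      member_seqs <- co$sequence[g$member_idx]
      expect_true(all(vapply(member_seqs, grepl, logical(1),
                             pattern = g$pattern, fixed = TRUE)))
      expect_true(all(nchar(member_seqs) >= nchar(g$pattern)))
      expect_true(g$pattern %in% member_seqs)
      expect_equal(g$counts,
                   colSums(co$counts[g$member_idx, , drop = FALSE]))
    }
  }
})

test_that("grouping is deterministic under input permutation", {
  co <- random_collapsed(55, n = 150L)
  pats <- select_patterns(co, n_patterns = 30L)
  res1 <- canonical_result(aggregate_groups(pats, co))
  perm <- sample.int(length(co$sequence))
  co2 <- co[perm]
  pats2 <- select_patterns(co2, n_patterns = 30L)
  res2 <- canonical_result(aggregate_groups(pats2, co2))
  expect_equal(res1, res2)
})

test_that("every formed group strictly shrinks the search set", {
  co <- random_collapsed(99, n = 200L)
  pats <- select_patterns(co, n_patterns = 30L)
  res <- aggregate_groups(pats, co)
  sizes <- vapply(res$groups, `[[`, integer(1), "n_members")
  expect_true(all(sizes >= 1L))  # each group removes at least its pattern
  expect_equal(sum(sizes) + length(res$ungrouped), length(co$sequence))
})

test_that("requantification quantifies fixed patterns, allowing empties", {
  co <- make_collapsed(list(s1 = c(TTTACGTTT = 4L, GGGG = 2L)))
  res <- requantify_groups(c("ACGT", "CCCCC"), co)
  pats <- vapply(res$groups, `[[`, character(1), "pattern")
  tot <- vapply(res$groups, `[[`, numeric(1), "total")
  expect_equal(tot[pats == "ACGT"], 4)
  expect_equal(tot[pats == "CCCCC"], 0)
  expect_equal(co$sequence[res$ungrouped], "GGGG")
})
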