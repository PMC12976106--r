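---
title: "Identifying Ribo-Seq contaminants and designing LNA blockers"
author: "ribosweep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying Ribo-Seq contaminants and designing LNA blockers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribosweep)
```

## The problem

Ribosome profiling sequences the ~20–32 nt mRNA fragments protected by
translating ribosomes. The nuclease digestion and gel purification steps
also release fragments of highly abundant non-coding RNAs — rRNA, tRNA,
sno/snRNA — that fall in the same size range and routinely consume half or
more of a library's reads. Because each fragment family is produced by
nuclease action on a particular organism, tissue and condition, fixed
commercial depletion panels miss many of them. The practical remedy is to
sequence a small pilot run, identify the experiment-specific contaminant
fragments, and block them in later libraries with locked-nucleic-acid
(LNA) oligonucleotides added during library amplification: the LNA binds
its target with high affinity and sterically halts the polymerase, no
extra purification step required.

`ribosweep` implements the computational side of that workflow: it turns
pilot-run alignments into ranked contaminant fragment groups, recommends
an LNA target sequence per group, predicts the payoff of a given blocker
set size, and quantifies how well a depleted re-run performed.

## The grouping procedure

Contaminant fragments from one nuclease-exposed site share a common core
but differ by ragged 5′/3′ ends, so they form *substring families*: the
shortest member of a family is contained in every other member. The
identification algorithm exploits this directly.

1. **Filter.** Mapped, primary alignments whose read length lies in
   \[`min_len`, `max_len`\] (default 20–30 nt, both inclusive — the
   footprint gel window) are kept, one record per read name, sequences
   restored to read orientation.
2. **Classify.** Each read is intersected with gene-level annotation
   features; a read overlapping any non-coding biotype is `noncoding`,
   reads overlapping only coding features are `mRNA`. Non-coding
   precedence is deliberate: the target of this tool is the contaminant
   pool, so sensitivity beats specificity here. Unknown biotypes also fall
   to non-coding (with a warning) for the same reason.
3. **Collapse.** Identical sequences become one record with per-sample
   counts.
4. **Select patterns.** The 10,000 most abundant collapsed reads (by
   cross-sample total) become matching patterns. Abundance ties break
   lexicographically so the selection is reproducible.
5. **Group greedily.** Patterns are processed shortest-first (ties:
   higher abundance, then lexicographic). The current pattern captures
   every remaining sequence that contains it as an exact substring
   (sense strand only — the library is stranded and matching is literal);
   the group's counts are summed over members; all members, including the
   pattern, are removed from the search set before the next pattern is
   examined. Each collapsed read therefore belongs to exactly one group,
   totals are conserved, and the group's *shortest common sequence* — the
   pattern — is both its label and the recommended LNA target.

The elimination step is what makes the procedure fast and
interpretation-friendly: a long fragment already explained by a shorter
core never seeds a redundant group. The implementation is observationally
identical to a naive re-scan with literal `grep` semantics; the test suite
verifies this equivalence against an independent brute-force reference on
hundreds of randomised inputs.

Two points were deliberately resolved where the procedure admits
variants. Patterns are selected from *all* collapsed reads, not only
non-coding-classified ones, because abundance ranking alone is what the
grouping needs; a `scope = "noncoding"` option restricts selection when a
conservative target list is wanted, and every group carries a
`dominant_biotype`/`dominant_category` label either way. Second, the
search set is the *entire* collapsed read set, not just the top-10,000
patterns, so low-abundance ragged variants still join their family.

## Blocker design

An effective LNA blocker alternates DNA and LNA nucleotides beginning
with DNA — so LNA sits at every even position — and carries a
3′-phosphate so it cannot act as a primer. `design_probe()` enforces this
architecture; lengths are bounded to \[14, 20\] nt by default (14 nt is a
reasonable specificity floor for a genome the size of Arabidopsis;
larger genomes may need longer probes). Longer targets are trimmed to the
`max_len` window whose GC fraction is closest to 0.5 (ties: leftmost), a
plain encoding of standard primer-design practice. Probes are antisense
by default; because blocking either strand of the amplicon suppresses
amplification, a sense option is equivalent and provided. `qc_probe()`
adds GC, homopolymer and (given a reference FASTA) exact-match
specificity checks; melting-temperature prediction for mixed LNA/DNA
duplexes depends on proprietary parameter sets and is intentionally out
of scope. `render_probe()` emits the vendor plain-text notation, e.g.
`G+CC+TG+GG+TG+TC+AC+A/3Phos/`.

## Reporting and the figure of merit

`percent_matrix()` tabulates the top `top_k` (default 10) groups as
percentages of each sample's total filtered reads, with per-column
cumulative sums — the numbers behind a contaminant heatmap.
`figure_of_merit()` reports, for every candidate blocker set size *k*,
the mean cumulative percentage of reads captured by the *k* most abundant
groups: the expected sequencing-depth payoff of ordering *k* LNAs. The
curve is non-decreasing by construction and its terminal value equals
the total grouped percentage. Percentages use post-filter totals as the
denominator — that is what the analysis can observe, and it matches how
the heatmap column sums are read.

## Evaluating a depletion run

`depletion_report()` compares an undepleted arm with a depleted arm:

* **Contaminant reduction** — the summed percentage of non-coding-dominant
  groups, averaged over each arm's samples; by default the depleted arm is
  requantified against the undepleted arm's patterns so both arms count
  the same targets. Both the relative reduction
  `100 × (1 − depleted/undepleted)` and the absolute percentage-point
  difference are reported, since either reading of "reduced by X%" may be
  wanted.
* **mRNA yield** — the percentage of reads classified mRNA and strictly
  longer than 20 nt; blocking contaminants at fixed sequencing depth
  raises this, which is the economic argument for depletion.
* **Gene-level correlation** — Pearson correlation of replicate-averaged,
  `log2(x + 1)`-transformed gene counts between arms. The shifted-log is
  used as a simple variance-stabilising transform; the comparison is a
  sanity check that depletion preserved relative gene quantification, not
  a differential-expression analysis, so a shrinkage estimator would add
  machinery without changing the conclusion.
* **qPCR abundance** — `qpcr_abundance()` converts a cycle-threshold
  difference to a percentage of the undepleted control,
  `100 × E^(Ct_control − Ct_treated)`, with efficiency `E` fixed at 2
  (perfect doubling) by default; a 10-cycle difference is a
  1024-fold (≈ >1000-fold) reduction.

## The simulator: what it emulates and what it does not

`simulate_experiment()` builds a complete synthetic test universe: random
chromosomes; non-overlapping rRNA/tRNA/snoRNA loci and protein-coding
genes written to GFF3; contaminant cores cut from (or embedded into) the
non-coding loci; and aligned reads written as coordinate-correct SAM, so
the whole pipeline runs without an external aligner.

Defaults define the simulated study conditions: five contaminant families
at library fractions 0.30, 0.15, 0.08, 0.04 and 0.02 (a 59% contaminant
burden, typical of an undepleted plant Ribo-Seq run), 20,000 reads per
library, cores of 20–24 nt, ragged 5′/3′ extensions of up to 3 nt drawn
from the flanking genomic sequence (so every family member contains its
core), mRNA footprints of 20–32 nt drawn from a log-normal per-gene
expression profile, and two replicates per arm. The bare core is always
emitted at least once per family, which is what lets the grouping recover
the exact core as a group's shortest member. In-silico depletion retains
core-containing reads with probability 1/1000 and resamples survivors to
the original depth — the fixed-read-budget renormalisation is exactly why
mRNA yield rises when contaminants are blocked.

The simulator deliberately omits sequencing errors, quality-score
realism, PCR duplicates, splicing, soft-clipping and multimapping
ambiguity. Passing tests on simulated data therefore demonstrate the
correctness of the algorithmic chain — filtering, classification,
collapsing, grouping, design, evaluation — under clean alignments; they
do not certify behaviour under alignment artefacts, which real pilot
runs should assess via the exported classification summaries.

## Numerical conventions and edge cases

* Coordinates are 0-based half-open internally; GFF 1-based inclusive
  input is converted on load.
* Substring matching is exact; `N` matches nothing. N-containing reads
  are retained but can only group with themselves.
* All tie-breaks (pattern length, abundance, lexicographic) are fixed, so
  identical inputs give identical outputs regardless of input order.
* Degenerate inputs fail loudly: empty annotations, manifests with
  duplicate ids, samples with zero totals, arms without mRNA reads, and
  correlation over fewer than 3 genes are errors; header-only manifests
  and unmapped-only files produce empty results with warnings.
* Problem sizes in the test suite (libraries of 3,000–20,000 reads,
  toy genomes of 2 × 60–100 kb, 50-replicate oracle comparisons at up to
  500 collapsed reads) were chosen so the full suite and the acceptance
  workflow each complete in a few minutes on a laptop; the algorithmic
  scaling to the 10–20 million-read pilot runs used in practice is linear
  in unique sequences per pattern pass.

## Known limitations

* Feature assignment is genomic-interval overlap at gene level; no
  splice-aware or transcript-model quantification (footprints are short
  and contaminant loci unspliced, so this is adequate for the purpose).
* Reverse-complement containment is not considered during grouping; a
  stranded small-RNA protocol is assumed.
* Probe specificity checking is exact-match counting, not a
  thermodynamic off-target model.
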