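# ribosweep

Contaminant identification and LNA blocker design for ribosome-profiling
(Ribo-Seq) libraries.

Ribo-Seq libraries co-purify abundant non-coding RNA fragments — rRNA,
tRNA, sno/snRNA pieces released by the footprint-generating nuclease —
in the same 20–30 nt size range as ribosome-protected fragments. These
contaminants are experiment-specific, so fixed depletion panels miss
them. `ribosweep` turns a small pilot sequencing run into a custom
depletion plan: it identifies the contaminant fragment families, reports
their per-sample abundance, recommends locked-nucleic-acid (LNA) blocker
target sequences, and quantifies how well a depleted re-run performed.
It is aimed at groups running Ribo-Seq in any organism with a GTF/GFF3
annotation.

## The core algorithm

After length filtering (20 ≤ L ≤ 30), annotation-based classification
and collapsing of identical reads into counted unique sequences, the
10,000 most abundant sequences are taken as matching patterns and
grouped greedily by substring containment, shortest pattern first:

1. sort patterns by ascending length;
2. the current pattern *p* captures every remaining sequence *s* with
   *p* ⊆ *s* (exact, contiguous, sense strand);
3. the group records the summed per-sample counts and its *shortest
   common sequence* (= *p*, the group's recommended LNA target);
4. all matched sequences are eliminated from the search set before the
   next pattern is queued.

Each unique sequence ends up in exactly one group, counts are conserved,
and ragged-ended fragment families collapse onto their common core.
Blockers designed against a group follow the alternating architecture
`5'-D +L D +L … D-3'-phosphate` (DNA first, LNA at even positions,
≥ 14 nt; the 3′-phosphate prevents priming). The *figure of merit*
reports, for each candidate blocker set size *k*, the cumulative
percentage of library reads captured by the top *k* groups — the
expected payoff of ordering *k* LNAs. Depletion runs are evaluated by
the relative reduction of the contaminant percentage
(100 × (1 − depleted/undepleted)), the change in mRNA yield
(mRNA reads > 20 nt), and the Pearson correlation of log2(x+1)
replicate-averaged gene counts between arms.

## Worked example

Everything below runs on the package's own simulator — no sequencing
data needed. Five contaminant families are planted at library fractions
30/15/8/4/2%:

```r
library(ribosweep)

cfg <- sim_config(seed = 11, n_chroms = 2, chrom_length = 60000,
                  n_coding_genes = 20, n_reads = 4000)
ex <- simulate_experiment(cfg, "demo")          # genome, GFF3, SAM, manifest
m  <- load_manifest(ex$manifest)

ident <- run_identify(m[!m$depleted, ], ex$annotation, "demo_out")
head(groups_table(ident$result), 6)
#> rank                  pattern length dominant_biotype n_members total
#>    1    AACCAGTGTCGCCTACCTTCG     21             rRNA        16  2395
#>    2   CGGCATGCTTCGGTTCGCATGG     22             rRNA        16  1210
#>    3     CGACAAATTTCGACTTCGAA     20             rRNA        16   615
#>    4  TACAGCACTCGGCGGTGACCGCC     23             tRNA        16   337
#>    5 GAATCTGGATCCAGCGGCAAGTTT     24           snoRNA        16   159
#>    6     ACTAAGCTGTGTAGTGTGTT     20   protein_coding        15    16
```

The five planted cores are recovered verbatim as the top five group
patterns (ranks 1–5, all non-coding; rank 6 is the most abundant mRNA
footprint). `ident$fom$cumulative_pct` gives the figure of merit —
`31.9 48.1 56.3 60.8 62.9 …` — i.e. five blockers would target ~63% of
the library. Probe design renders order-ready sequences:

```r
ps <- run_design("demo_out/groups.tsv", "demo_design")
ps$probes[[1]]
#> LNA_Top_1 (20 nt, antisense): G+AA+GG+TA+GG+CG+AC+AC+TG+GT+T/3Phos/
```

Evaluating the simulated depleted arm (in-silico blocking at factor
1000, resampled to constant depth):

```r
run_evaluate(m, ex$annotation, "demo_eval")
#> depletion_report:
#>   contaminants: 62.91% -> 0.12% (relative reduction 99.8%, 62.8 points)
#>   mRNA yield:   33.89% -> 91.09% (ratio 2.69)
#>   gene-level Pearson r = 0.9905 over 20 genes
```

Contaminants collapse, the usable footprint yield rises ~2.7-fold at the
same sequencing depth, and gene-level quantification is preserved.

A thin command-line wrapper over the same functions is installed at
`inst/scripts/ribosweep-cli.R` with subcommands `identify`, `design`,
`evaluate` and `simulate`.

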