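Package: ribosweep
Title: Contaminant Identification and LNA Blocker Design for Ribo-Seq Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies experiment-specific non-coding RNA contaminants in
    ribosome profiling (Ribo-Seq) libraries from aligned reads, groups
    co-purifying fragments by greedy substring containment, designs locked
    nucleic acid (LNA) blocker oligonucleotides against the most abundant
    contaminant groups, and evaluates depletion performance between
    undepleted and depleted sample sets. Includes a fully deterministic
    simulator (toy genome, GFF3 annotation, aligned reads with planted
    contaminant fragment families, in-silico depletion) for end-to-end
    testing without real sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    GenomeInfoDb,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    grDevices,
    graphics,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
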