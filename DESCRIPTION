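Package: WGDinfer
Title: Branching-Process Inference of Whole-Genome Doubling and
    Loss-of-Heterozygosity Sculpting Statistics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models arm-level copy-number evolution in tumours as a
    branching process in which each chromosome-arm copy is deleted,
    retained or duplicated per time period, constructs exact copy-number
    distributions by probability generating function composition, and
    compares models with and without a single whole-genome doubling (WGD)
    event by maximum likelihood and the Akaike Information Criterion.
    Also summarises allelic imbalance and loss of heterozygosity (LOH)
    genome-wide from allele-specific copy-number segments, calls acquired
    LOH between early and late samples of a patient, detects mirrored
    allelic imbalance from B-allele frequencies, and computes LOH
    "sculpting" statistics: codon-usage-based expected non-synonymous
    counts, a one-sided binomial excess test, neoantigen-loss accounting
    per LOH event, and a two-sided unconditional exact (Barnard) test for
    mutual exclusivity of neo-antigenicity and mutation load. A
    synthetic-cohort generator produces complete multi-sample patients so
    the whole pipeline is testable without access-controlled data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: CopyNumberVariation, SomaticMutation, StatisticalMethod
RoxygenNote: 7.3.3
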