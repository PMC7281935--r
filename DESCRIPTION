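Package: nccmscan
Title: Non-Coding Constraint Mutation Analysis for Tumor Whole-Genome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and characterizes non-coding constraint mutations
    (NCCMs) in matched tumor/normal whole-genome cohorts: somatic-call
    filtration (caller concordance, panel of normals, germline databases with
    somatic whitelisting), per-gene query territories (UTRs, introns, and
    +/- 100 kbp intergenic flanks), constraint-threshold NCCM calling,
    length-normalized per-gene rates with a key-gene versus other
    protein-coding-gene enrichment test, regulatory-track annotation,
    biophysical transcription-factor binding-affinity deltas for
    variant-centered windows, promoter hotspot recurrence and mutual
    exclusivity, and trinucleotide mutational-signature refitting. Ships a
    deterministic synthetic-study generator (toy genome, constraint track,
    paired-caller VCFs with planted enrichment) so the whole pipeline is
    testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    pracma
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
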