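Package: omnivar
Title: Comprehensive Variant Detection from Aligned Short Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-pass detection of SNVs, indels, structural variants
    (deletions, duplications, insertions, inversions, translocations) and
    read-depth copy-number variants from coordinate-sorted BAM files of
    paired-end short reads. Per-reference-base evidence (physical coverage,
    allele counts, soft-clip, split-read and discordant-pair signals) is
    collected in one pass, breakpoint evidence is clustered with an adaptive
    length tolerance driven by the library insert-size distribution,
    candidate breakpoints are scored with a binomial mismapping model, and
    matched start/end breakpoints are emitted as VCF calls. Includes an
    optional inline duplicate-pair filter, a paired-end read simulator with
    planted variants for fully self-contained testing, and a benchmark
    harness implementing reciprocal-overlap and breakpoint-tolerance
    matching rules.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
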