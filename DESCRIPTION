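Package: paircall
Title: Read-Pair Concordant Variant Calling for Fully Overlapping
    Amplicon Sequencing
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Calls single nucleotide variants and small indels from
    short-insert PCR-amplicon paired-end sequencing in which both reads
    of a pair span the entire primer-intervening insert. A variant
    contributes evidence only when it is observed identically in both
    mates of a read-pair, which suppresses sequencing-chemistry errors;
    primer-derived positions are removed using mapping and design
    coordinates rather than sequence matching. Calls are filtered by an
    absolute read-pair count, a read-pair proportion, and optionally a
    base-quality threshold. The reference sequence is recovered from
    CIGAR strings and MD tags, so no reference FASTA is needed. Includes
    a synthetic amplicon data generator with planted variants for
    validation, a per-amplicon coverage report, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    methods,
    optparse,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
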