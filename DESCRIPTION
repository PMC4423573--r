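Package: homeoSort
Title: Subgenome Read Categorization for Allopolyploids
Version: 0.1.0
Authors@R:
    person("homeoSort", "Developers", email = "homeosort@example.org",
           role = c("aut", "cre"))
Description: Assigns sequencing reads from an allopolyploid to their
    subgenome of origin. Implements three complementary strategies: a
    dual-reference method that maps the same read set to each diploid
    relative's reference and compares the two alignments of every fragment
    through four serial criteria (unique mapping, MAPQ, aligned length,
    exact matches); a homoeo-SNP vote method that categorizes fragments
    mapped to a single reference by majority vote over diagnostic SNP
    positions; and a concatenated-reference baseline. Also provides an
    iterative homoeo-SNP index builder from categorized read pileups,
    diploid-read error-rate estimation, and a fully deterministic synthetic
    allopolyploid simulator (genome evolution, paired-end reads with truth
    labels, and a naive unique-best mapper) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
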