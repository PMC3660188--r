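Package: dyz1kit
Title: In Silico Characterization of Human Y-Chromosome DYZ1 Satellite Arrays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for desk-top characterization of the human Y-chromosome
    DYZ1 satellite repeat and the male-specific region of the Y (MSY).
    Decomposes ~3.56 kb DYZ1 HaeIII units into in-frame TTCCA pentamers and
    their Hamming-distance derivative classes, performs IUPAC-aware virtual
    restriction digestion with lost/gained site comparison and PCR-RFLP
    fragment prediction, tallies substitutions and indel events from global
    pairwise alignments, predicts amplicons for sequence-tagged-site (STS)
    deletion mapping with configurable AZF deletion signatures, and fits
    qPCR standard curves for absolute copy-number quantification normalized
    to genome equivalents. A seeded synthetic-data generator produces every
    input class with retained ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    seqinr,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
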