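Package: micrfilter
Title: Filtering Microhomology-Induced Chimeric Read Artifacts in FFPE Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-hoc filtering of called somatic mutations from
    formalin-fixed paraffin-embedded (FFPE) sequencing libraries.
    Single-stranded DNA in FFPE extracts forms chimeric molecules during
    library end-repair, either by fold-back at proximal palindromic
    sequences or by mis-annealing of distant homologous regions; the
    resulting chimeric reads carry false mutations with a characteristic
    positional bias. Given a mutation list, a BAM file and the reference
    genome, the package classifies each mutation as a true variant or a
    chimeric-read artifact using a multinomial test on supporting-length
    distributions, exact reverse-complement search for local palindromes,
    and exact genome-wide search for distant homologous 40-mers. A
    synthetic-fixture simulator generates toy genomes and aligned reads
    with planted artifacts and truth labels for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
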