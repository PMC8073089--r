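Package: mitotiler
Title: Tiled-Amplicon Mitochondrial DNA Simulation and Forensic Haplotyping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An open, testable implementation of a forensic mitochondrial DNA
    tiled-amplicon workflow. Models the circular human mtDNA reference and its
    named regions, designs staggered two-set tiled amplicon panels, simulates
    dual-indexed paired-end sequencing libraries (haplotypes, heteroplasmy,
    two-person mixtures, no-template controls, NUMT contamination, index
    crosstalk and run carryover), demultiplexes by dual index, aligns reads to
    the circular reference with a seeded banded aligner, applies forensic
    read-level filters (Q30 masking, short-byproduct removal, primer trimming,
    NUMT exclusion, HVII C-stretch reverse-strand soft-clipping), calls
    variants under analytical and interpretation thresholds with SWGDAM-style
    nomenclature, derives thresholds from control runs, and emits
    interpretation reports (mixtures, contamination, concordance,
    EMPOP-compatible output).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Rsamtools,
    optparse
Config/testthat/edition: 3
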