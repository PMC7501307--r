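Package: aaopt
Title: Minimal Binary-Feature Classification of the Proteinogenic Amino Acids
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Finds minimal sets of five numeric physicochemical features that
    uniquely classify the 20 proteinogenic amino acids by repeated binary
    separation, either at the median or at high-gap cut points. Provides an
    AAindex1 flat-file reader, gap-ranked scoring of candidate separations, a
    capacity-pruned backtracking search for all five-feature solutions with a
    brute-force verification oracle, leave-one-residue-out redundancy
    profiling, empty-niche assessment of candidate non-canonical amino acids,
    a synthetic table generator with planted classifications, and DOT/TSV/JSON
    exports plus a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
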