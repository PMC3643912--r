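Package: segdig
Title: Sex-Biased Gene Classification for Two-Library RNA-seq Designs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Expression quantification and sex-biased gene classification for
    replicate-free RNA-seq designs with one library per group per developmental
    stage, as used in gonadal transcriptome studies of genotypic XX/XY fish.
    Implements RPKM quantification, the Audic-Claverie exact two-library count
    test with Benjamini-Hochberg false discovery rate control, the five-type
    per-stage gene classification (co-expressed, XX-/XY-differential,
    XX-/XY-specific, and non-significant specific genes), and cross-stage
    derivation of sex-specific, all-stage co-expressed, and sex-enhanced gene
    sets. Includes a Poisson count simulator with planted gene classes and
    ground truth for validating the whole pipeline without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
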