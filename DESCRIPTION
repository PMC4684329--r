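Package: helpdm
Title: Paired Differential Methylation Analysis for CCGG-Fragment (HELP-Style) Methylomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for restriction-enzyme methylome profiling of
    paired tumor and adjacent non-tumor tissue. Defines CCGG-bounded fragment
    loci by in-silico MspI digest, assigns promoter/gene-body/intergenic
    compartments and CpG-island/shore subcompartments, performs per-locus
    paired t-tests with Benjamini-Hochberg false-discovery-rate control,
    tests compartment over-representation of differentially methylated loci
    by permutation, merges differential methylation with differential
    expression under 2 kb location rules with canonical/non-canonical
    accounting, and evaluates top-k locus classifiers under repeated
    train/test splits. Includes a synthetic-data generator with planted
    ground truth for end-to-end recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    methods,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
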