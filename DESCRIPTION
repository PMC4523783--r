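Package: coldmiR
Title: Discovery of Cold-Inducible miRNAs from Two Small RNA Libraries
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end small RNA-seq analysis workflow for identifying
    cold-inducible microRNAs in grapevine from a pair of sequencing libraries
    (non-cold-treated and cold-treated) without biological replicates. Covers
    read cleaning and tag collapsing, exact-match genome annotation with
    non-coding RNA exclusion, known-miRNA identification with mismatch-tolerant
    matching against a mature reference, novel-miRNA discovery by hairpin
    excision, folding and a ten-rule precursor criteria check, two-library
    differential expression with TPM normalisation and an Audic-Claverie exact
    test, plant-style miRNA target-site scoring with RACE cleavage-site
    summarisation, and miRNA-target expression anti-correlation. Includes a
    ground-truth synthetic data generator emulating the study design for
    validation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'utils.R'
    'fold.R'
    'syn-data.R'
    'tagproc.R'
    'annotate.R'
    'known.R'
    'novel.R'
    'dem.R'
    'targets.R'
    'pipeline.R'
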