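Package: prenataldx
Title: Simultaneous Low-Pass CNV and Exome Trio Diagnostics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for joint copy-number and sequence-variant diagnosis of
    fetal structural anomalies from parent-fetus trios. Implements read-depth
    CNV calling from shallow whole-genome sequencing (20 kb bin counts,
    batch-median normalization, smoothed first-order-difference breakpoint
    detection and paired-breakpoint segment assembly), a simplified
    XHMM-style exonic CNV caller (PCA-normalized exon depths decoded with a
    3-state Viterbi and a minimum 3-contiguous-exon rule), variant quality
    screening, trio inheritance classification with CNV+SNV
    compound-heterozygous detection and double-diagnosis flagging,
    information-content phenotype prioritization over an HPO-style ontology,
    and cohort diagnostic-yield statistics with an exact two-tailed Fisher
    test. A fully specified synthetic trio-cohort generator with known
    ground truth makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
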