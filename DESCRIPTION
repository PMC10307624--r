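Package: phosphokin
Title: Phosphosite Quantification, Cross-Species Site Transfer and
    Kinase Activity Inference for Phosphoproteomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An inference chain for quantitative phosphoproteomics of
    ligand-stimulated time-course designs. Peptide-level intensities are
    grouped into phosphorylation site groups, median-normalized across
    runs, tested for differential abundance per contrast with
    Benjamini-Hochberg correction, and collapsed to a single fold change
    per phosphosite. Phosphosite positions are transferred between
    orthologous proteins by affine-gap Needleman-Wunsch global alignment.
    Kinase activities are inferred as substrate-set z statistics against
    the sample-wide fold-change background, and significant
    phosphoproteins are assembled into score-thresholded interaction
    networks with hypergeometric functional enrichment and redundancy
    pruning. A synthetic-data generator with recorded ground truth
    supports calibration and recovery studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    methods,
    Rcpp,
    Biostrings,
    fgsea,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
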