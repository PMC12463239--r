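Package: maepitope
Title: Epitope Assembly, Binding-Motif Discovery and HLA Deconvolution for
    Mild-Acid-Elution Immunopeptidomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns mild-acid-elution (MAE) immunopeptidomics peptide lists from
    genetically related cell lines into MHC class I and class II epitope sets,
    allele-specific binding-motif consensus sequences, and epitope-to-HLA-allele
    assignments. Implements replicate-consistency filtering, condensation of
    overlapping peptides into maximal epitopes, spectral-count abundance indices
    (Peptide Index and Epitope Index), centroid-linkage hierarchical clustering of
    epitope abundance profiles, gapless offset alignment of epitope nodes,
    positional logo scoring with significance thresholds, genotype-based allele
    deconvolution, precision benchmarking against external binder predictions,
    and a synthetic consanguineous-family peptidome generator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
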