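Package: indelscope
Title: Microhomology-Annotated Indel Signatures and Repair-Pathway Screens
    for Cas9 Amplicon Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for profiling DNA double-strand-break repair outcomes from
    CRISPR-Cas9 amplicon sequencing and arrayed flow-cytometry screens. Reads
    are aligned to an amplicon reference and collapsed into canonical,
    microhomology-annotated indel signatures; per-sample indel profiles are
    filtered, downsampled and summarized; repair-deficient clones are detected
    by symmetrized Kullback-Leibler divergence between profiles, classical
    multidimensional scaling, a bivariate-normal control null with chi-squared
    p-values and a replicate-consistent FDR rule; plate-structured
    percent-positive flow matrices are normalized by per-plate z-scoring,
    rank-2 PCA regression and control-referenced z-scores. A synthetic-data
    generator emulates clones with shifted balance between non-homologous and
    microhomology-mediated end joining, read sampling at configurable depth,
    and batch-structured flow plates, with exported ground truth for recovery
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
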