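Package: noisevolve
Title: Expression Noise Quantification, FACS Noise-Enrichment Simulation,
    and Bulk-Segregant Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying gene-expression noise from dual-reporter
    flow cytometry (gating, Fano factor, intrinsic/extrinsic noise
    decomposition), simulating a FACS-based experimental-evolution protocol
    that enriches for high-noise mutant lineages by repeatedly sorting the
    outermost cells of the two-reporter intensity distribution, and mapping
    causal mutations by bulk-segregant analysis with the QTL-seq SNP-index
    and delta-SNP-index statistics. A seeded synthetic-data module generates
    every input the pipeline consumes: cytometry event tables with intrinsic
    and extrinsic lognormal noise components plus debris/doublet
    contamination, F1 haploid crosses with Haldane recombination, pooled
    sequencing read counts, logistic growth curves, and polysome absorbance
    traces. Small assay helpers cover qPCR fold change (2^-ddCt), maximal
    growth rate, polysome-to-monosome ratio, and normalized competition
    fitness.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
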