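Package: pleiosim
Title: Simulation of Pleiotropic, Linked and Epistatic Phenotypes from Marker Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates single and multiple quantitative traits from real or
    synthetic biallelic marker data. Traits are controlled by user-configured
    additive, dominance, and additive-by-additive epistatic quantitative trait
    nucleotides (QTNs) under pleiotropy, partial pleiotropy, or LD-mediated
    spurious pleiotropy. Genetic correlations between traits can be imposed
    exactly via a Cholesky whitening/coloring transformation, residual
    variances are calibrated from per-trait heritabilities, and residual
    correlations are optionally simulated. Reads HapMap, VCF, Plink ped/map
    and numeric marker formats, writes GEMMA- and TASSEL-compatible phenotype
    files, and records full provenance (QTN maps, realized LD, realized
    heritabilities and correlations, seeds) for downstream GWAS and genomic
    selection benchmarking. A built-in fixture generator produces genotype
    panels with tunable minor-allele-frequency spectra and LD-block structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 3.5)
Imports:
    stats,
    utils,
    tools,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
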