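Package: rohscan
Title: Genotype-Likelihood Runs of Homozygosity, Inbreeding and Diversity for Sparse Capture Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects runs of homozygosity (ROH) from genotype likelihoods on
    sparse hybridization-capture SNP panels and summarizes genomic inbreeding
    and diversity for wild populations. Implements a windowed likelihood-ratio
    ROH scan, F_ROH inbreeding coefficients with nonparametric bootstrap
    confidence intervals, coalescent-age dating of ROH from linkage-map
    genetic lengths with generation binning, site-allele-frequency based
    folded site-frequency-spectrum estimation and nucleotide diversity,
    Weir-Cockerham F_ST, the standard site- and individual-level SNP
    filtering ladder, and interval-arithmetic capture-target design filters.
    A synthetic-cohort generator plants identical-by-descent tracts of known
    coalescent age in simulated genomes so every stage can be validated
    against exact truth sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
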