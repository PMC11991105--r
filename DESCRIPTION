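Package: islandadapt
Title: Landscape Genomics of Island Tree Populations: Sweep Scans,
    Environmental Association and Risk of Non-Adaptedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for detecting adaptive genetic
    variation in structured natural populations from whole-genome SNP
    data. Implements SNP-level quality filters (missingness, minor
    allele frequency, windowed linkage-disequilibrium pruning), a
    composite mu-statistic selective-sweep scan combining polymorphism
    deficit, site-frequency-spectrum shift and flanking-LD signatures,
    latent-factor-corrected genotype-environment association tests with
    genomic-inflation calibration and Storey q-values, and Risk of
    Non-Adaptedness (RONA) projections of allele-frequency displacement
    under future climate scenarios. Ships a synthetic-data generator
    (Balding-Nichols structured genotypes, environmentally associated
    loci, forward Wright-Fisher hard sweeps) used for calibration and
    power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
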