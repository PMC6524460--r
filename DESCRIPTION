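Package: cryoflux
Title: Glacier Retreat, Cryoconite Coverage and Microbial Flux Budgets for
    Glacier-Fed Antarctic Lakes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A quantitative pipeline linking a retreating glacier to the
    microbiome of an adjacent perennially ice-covered lake. Estimates
    terminus retreat rates and swept melt volumes from digitized
    glacier-lake boundaries and a bathymetric grid, measures fractional
    cryoconite-hole coverage on glacier-surface imagery with a
    roundness-filtered segmentation, combines the two into volumetric flux
    budgets, analyses amplicon (RSV/ASV) count tables (negative-control
    filtering, alpha diversity, Bray-Curtis ordination, permutation tests,
    differential abundance, habitat genus sharing), and apportions sink
    communities among candidate sources with a collapsed-Gibbs
    Dirichlet-multinomial source-tracking sampler. A synthetic-data module
    generates every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    pracma,
    EBImage,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png
Config/testthat/edition: 3
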