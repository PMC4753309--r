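Package: ferromat
Title: Assembly and Succession Analytics for Fe(III)-Oxide Microbial Mats
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of biomineralized Fe(III)-oxide microbial
    mat assembly and succession in acidic geothermal springs. Fits first-order
    exponential models to iron-oxide accretion and DNA-biomass time series,
    models steady-state oxygen microprofiles with a dimensionless
    reaction-diffusion slab solution (diffusive flux, Thiele modulus,
    penetration depth), estimates early colonization rates from electron
    microscopy field counts, analyses 16S community succession (copy-number
    corrected relative abundance, Bray-Curtis clustering, taxon decline rates,
    amplicon primer-bias diagnostics, a four-stage mat classifier), and
    converts oxalate-extraction elemental data to areal loadings and
    oxyanion-to-iron molar ratios. A synthetic-data generator reproduces the
    statistical structure of every input type so the full pipeline is testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    vegan,
    ape,
    yaml,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Microbiome, Metagenomics, Software, TimeCourse
RoxygenNote: 7.3.3
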