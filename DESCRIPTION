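Package: TempoPopGen
Title: Temporal mtDNA Diversity and Demographic Scenario Testing by ABC
    Random Forests
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for genetic time-series analysis of single-locus
    (mitochondrial) sequence data sampled from one population at several
    time points. Provides alignment import and validation, site
    classification and haplotype collapsing, the classical diversity and
    neutrality statistics (haplotype diversity, nucleotide diversity,
    Watterson's theta, Tajima's D, Achaz's Y), Hudson's FST and AMOVA
    phiST with permutation tests, sample-size standardisation of any
    statistic by with-replacement rarefaction, a serial-sampling
    (heterochronous) coalescent simulator with piecewise-constant
    population size and finite-sites mutation, a six-scenario demographic
    prior engine, approximate Bayesian computation model choice by random
    forests with linear-discriminant augmentation and out-of-bag
    diagnostics, and goodness-of-fit envelope tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    MASS,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ape
biocViews: PopulationGenetics, Coalescent, Classification, Bayesian
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'alignment-io.R'
    'popgen-stats.R'
    'utils.R'
    'coalescent.R'
    'scenarios.R'
    'abc-rf.R'
    'gof.R'
    'rarefaction.R'
    'pipeline.R'
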