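Package: dkoscreen
Title: Monte Carlo Simulation and Scoring of Double-Knockout CRISPR Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates growth-based single- and double-knockout CRISPR
    screens with known ground-truth genetic interactions. Cell division is
    modelled per doubling cycle by a multinoulli distribution parameterised
    by per-gene fitness phenotypes; dual knockouts combine the two
    single-knockout division variables under independence, and genetic
    interactions are injected by resampling ("jiggling") the phenotypes of
    flagged gene pairs. Guide libraries are allocated by Dirichlet draws,
    populations grow by multinomial resampling and pass through
    multivariate-hypergeometric bottlenecks with Poisson
    multiplicity-of-infection retention. The package scores simulated
    screens with delta log fold change (dLFC/zdLFC) against the simulated
    truth and reports Pearson correlation, precision/recall at k, area
    under the precision-recall curve, read-concentration and replicate
    reproducibility metrics, so that library designs (coverage, guide
    efficacy, guides per gene, initial-count dispersion, cell doublings,
    interaction magnitude) can be profiled systematically.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
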