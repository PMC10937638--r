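Package: wbmflux
Title: Host-Microbiome Whole-Body Constraint-Based Modelling of Urinary Metabolite Secretion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds personalised gut-microbiome community metabolic models from
    species relative abundances, attaches them to the large-intestinal lumen of
    an organ-resolved whole-body host model, and interrogates the joint model
    by flux balance and flux variability analysis: maximal urine secretion
    fluxes, microbial secretion capacities, host-microbiome co-metabolism
    decomposition, diet-supplementation and reaction-deletion screens including
    minimal deletion-set search. Includes pan-species model construction as the
    union of strain reconstructions, diet constraint application in
    mmol/person/day, gOTU count-table processing into model-ready relative
    abundances, and the accompanying statistics (probabilistic quotient
    normalisation, covariate-adjusted robust regressions with Wald tests and
    Benjamini-Hochberg FDR, fractional abundance regressions, log-ratio tests).
    Ships seeded synthetic generators for toy fermenting strains, a toy host
    embodying the main formate-producing pathways, abundance tables with
    planted group shifts, and log-normal metabolome tables, so the whole
    pipeline is testable offline. The linear-programming core is a
    bounded-variable primal simplex implemented in the package.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    xml2,
    sandwich,
    lmtest,
    stats,
    utils
Suggests:
    biomformat,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
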