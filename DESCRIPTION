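Package: koxfba
Title: Constraint-Based Flux Analysis of Klebsiella oxytoca 2,3-Butanediol Production
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based analysis of metabolic network models,
    built around the 2,3-butanediol (2,3-BD) fermentation metabolism of
    Klebsiella oxytoca. Provides a constraint-based model container with
    gene-protein-reaction (GPR) rules, JSON/TSV model formats and a restricted
    SBML Level 3 (fbc) importer, flux balance analysis under the pseudo-steady
    state assumption via a built-in bounded-variable simplex solver,
    lexicographic objectives, flux variability, reaction and gene essentiality,
    oxygen flux-response curves and product/byproduct flux solution-space
    surfaces, single-gene knockout scanning and ranking, precursor-pool
    augmentation by consumer elimination, a biomass-composition-to-reaction
    builder (GC-content derived nucleotide fractions, growth and non-growth
    associated maintenance), a curated central-metabolism fixture model of
    K. oxytoca containing the budB/budA/budC pathway, and fermentation
    summary metrics (OD600 to dry cell weight, yields, productivities and
    theoretical-yield fractions).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
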