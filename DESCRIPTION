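Package: abcselect
Title: Analysis of Directed-Evolution Selections on ABC Transporter Mutant Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to analyse fluorescence-activated cell sorting (FACS) selections on
    error-prone PCR mutant libraries of ABC transporter transmembrane regions.
    Simulates Poisson-load mutant clone libraries with planted additive phenotype
    effects and two-channel log-normal cytometry; calls amino-acid substitutions
    against an in-frame wild-type reference and builds mutations-per-position
    spectra; tests the spectrum against a Poisson null (chi-square goodness of fit)
    and calls enriched positions by a fold-over-null tail rule; inverts an exact
    combinatorial model of sequence space to estimate the mutational target size for
    altered substrate specificity; normalizes autocrine reporter measurements,
    decomposes multi-mutant signals into additive single-mutation contributions with
    epistasis residuals, and enumerates stepwise evolutionary trajectories; and
    simulates iterative quantile-gated sort-and-expand enrichment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
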