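Package: ferrodom
Title: Molecular Analysis of Iron-Incubated Marine Dissolved Organic Matter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end workflow for ultrahigh-resolution mass spectrometry
    (FT-ICR-MS) studies of solid-phase extractable dissolved organic matter
    (SPE-DOM) in iron-amendment incubation experiments. Provides molecular
    formula assignment from negative-mode electrospray peak lists under a
    CHNOSP(Cl,Fe) composition grid with homologous-series resolution and
    13C-isotopologue verification; per-formula molecular indices (DBE, modified
    aromaticity index, nominal oxidation state of carbon, van Krevelen compound
    classes); a multi-stage data-reduction cascade (elemental rules, blank and
    contaminant subtraction, spectral smoothing, replicate intersection);
    intensity-weighted sample summaries including the degradation index I_DEG
    and Rao's-entropy functional diversity; volume- and carbon-weighted
    endmember mixing reconstruction of incubation starting solutions; sample
    ordination and formula-covariate correlation screens; and a fully
    parameterised synthetic-spectrum generator with known ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    yaml
LinkingTo: Rcpp
Suggests:
    mzR,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
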