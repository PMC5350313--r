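Package: dyssync
Title: Severity Grading of Cardiac Mechanical Dyssynchrony from Gated
    Blood-Pool Image Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for automated grading of cardiac mechanical dyssynchrony
    from gated equilibrium radionuclide angiography (ERNA) image series.
    Implements factor analysis of dynamic structures (FADS) on the
    pixel-by-frame time-activity matrix, first-harmonic Fourier phase
    imaging with circular phase-histogram statistics, count-based left
    ventricular ejection fraction, aggregation of ordinal expert codes into
    consensus labels, and a two-stage cascade of linear support vector
    machines (absent versus present dyssynchrony, then mild versus
    moderate-severe) fed by FADS coefficient curves and clinical
    covariates. A synthetic gated-series cohort generator with Poisson
    count noise provides reproducible test beds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    RNifti,
    tiff,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
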