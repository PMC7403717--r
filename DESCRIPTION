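Package: apicalpulse
Title: Quantification of Pulsatile Apical Constriction and Ratcheting in
    Epithelial Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify pulsatile apical constriction and ratcheting
    from per-cell area time series of gastrulating epithelia, as measured
    during Drosophila ventral furrow formation. Provides gap interpolation,
    moving-average smoothing, constriction-rate computation, cubic
    polynomial detrending, local-extrema pulse detection, a per-cell
    ratchet statistic (mean area difference between consecutive pulsation
    peaks), behaviour categorization, peak-triggered averaging, and
    two-stage per-embryo averaging. Image-side utilities implement a
    grid-based confocal surface-projection algorithm with height-map
    extraction, background-estimation rules, apical mean projections,
    intensity time courses, per-cell intensity measurement, cell geometry,
    and Pearson colocalization. A statistical layer supplies an effect-size
    rule based on Cohen's d with a maximal-SD denominator, two-sample
    t-tests, one-way ANOVA with Tukey post hoc comparisons, and fold-change
    normalization. A synthetic-data module generates pulsatile traces, cell
    cohorts, labelled intensity movies, and 3D surface phantoms with known
    ground truth so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
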