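Package: leafdyn
Title: Integrated Modelling of Leaf Tissue Growth and Cell Division
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulation of a growing two-dimensional leaf tissue
    ("canvas") in which specified anisotropic growth rates, oriented by a
    proximodistal polarity field, are set by regulatory factors (PGRAD, MID,
    LAM, a diffusible proximal mobile factor PMF, and temporal factors LATE
    and EARLYGROWTH), together with a stochastic cell-division engine in
    which polygonal virtual cells anchored to the canvas divide by a noisy
    shortest-wall (Errera) rule once a competence zone and a sampled area
    threshold permit.  Includes model presets for the epidermal and
    subepidermal early-stage models, late-stage mature, limit-free and
    limiting-cell-size variants with division-threshold, growth-rate and
    timing mutants, tracking-style quantifications (clonal areal and
    directional growth rates, division statistics, competence classes,
    polygon-topology distributions), and a synthetic tracking-data
    generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
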