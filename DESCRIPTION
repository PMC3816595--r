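Package: dirprop
Title: Deformable Image Registration and Contour Propagation for Adaptive Radiotherapy
Version: 0.1.0
Authors@R:
    person("dirprop", "developers", email = "dirprop@example.org", role = c("aut", "cre"))
Description: Toolkit for deformable image registration (DIR) of longitudinal
    thoracic CT and automatic propagation of regions of interest (ROIs) for
    adaptive radiotherapy. Implements three registrars: fast-symmetric Demons
    (intensity/optical-flow forces with Gaussian field regularisation),
    Morphons (quadrature-filter local-phase differences with certainty
    weighting), and salient-feature-based registration (scale-space interest
    points matched and interpolated by 3-D thin-plate splines). ROIs are
    carried between scans either by displacement-field pull-back of binary
    masks or by transforming contour-mesh vertices. Includes the standard
    contour-agreement metrics (Dice score, mean slicewise Hausdorff distance,
    centre-of-mass shift, volume-change statistics, one-way ANOVA,
    point-biserial correlation), a synthetic thorax phantom with analytic
    ground-truth deformation fields for validation, NIfTI-1 / MetaImage / OBJ
    / PLY readers and writers, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
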