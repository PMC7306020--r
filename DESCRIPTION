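Package: ogdenlam
Title: Ogden Hyperelastic Identification and Finite-Element Preprocessing
    for Pelvic-Floor Biomechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale pipeline for the material-identification and
    model-quality computations used in childbirth finite-element studies of
    the levator ani muscle. Generates and reduces uniaxial tensile tests on
    soft tissue to nominal stress-stretch curves, identifies two-term
    incompressible Ogden hyperelastic constants by bounded multistart
    least squares under the stability constraint sum(mu_j * alpha_j) > 0,
    summarizes specimen cohorts, audits tetrahedral meshes against
    element-quality acceptance criteria (aspect ratio, dihedral angles,
    edge lengths, scaled Jacobian), and parameterizes station-indexed
    fetal-head descent trajectories for occiput-posterior and
    occiput-anterior presentations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
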