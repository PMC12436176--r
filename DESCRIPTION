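Package: hffm
Title: Functional Multi-Segment Foot Model Kinematics for Clinical Gait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes multi-segment foot kinematics from labeled 3D marker
    trajectories using a functionally motivated four-segment foot model
    (shank, hindfoot, forefoot, hallux). Joint centers inside the foot (heel
    rotation center, midfoot joint center) are obtained from published
    regression formulas, the metatarsal rotation axis from a gravity-referenced
    construction, and segment coordinate systems from the resulting joint
    parameters. Provides Euler-Cardan joint angles in the
    sagittal/frontal/transverse sequence, phenomenological foot angles
    (medial longitudinal arch, arch inclination, subtalar eversion,
    metatarsal I-V splay), trajectory smoothing, gait event detection,
    gait-cycle normalization, summary statistics, an equinovarus
    classification rule based on the early slope of hindfoot/shank flexion,
    group comparison statistics (one-way ANOVA with Bonferroni correction
    over mean/max/ROM), and a rigid-body synthetic gait generator with
    deformity presets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
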