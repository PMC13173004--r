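Package: mrpat
Title: Mid-Range Proton Arc Therapy Planning Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Treatment-planning toolkit for pencil-beam-scanning proton arc
    therapy built around mid-range energy-layer selection: a single energy
    layer per gantry control point whose Bragg peak sits at the
    water-equivalent mid-point of the target along each beam direction.
    Provides voxelized phantom construction, Siddon ray tracing of
    water-equivalent path length, an analytic Bortfeld-type pencil-beam dose
    and track-LET engine with dose-averaged LET accumulation, McNamara
    variable-RBE weighted dose, nonnegative spot-weight optimization with
    quadratic objectives, DVH and hotspot-percentile evaluation,
    scenario-based robustness analysis over range and setup uncertainty, and
    an additive delivery-time model, with full-range arc and two-beam IMPT
    comparator strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
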