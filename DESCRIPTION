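Package: ventpace
Title: Biopacemaker Simulation in Human Ventricular Tissue by IK1 Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates engineered biopacemakers created from human ventricular
    endocardial myocytes whose inward-rectifier potassium current (IK1) is
    suppressed to unmask spontaneous automaticity. Provides the ten Tusscher-
    Panfilov (2006) human ventricular cell model (endocardial, mid-myocardial
    and epicardial variants) and the Stewart et al. (2009) Purkinje fibre cell
    model with the maximal IK1 conductance as a first-class tunable parameter,
    a 2D monodomain reaction-diffusion solver on labelled grids with per-edge
    coupling masks (electrical insulation), procedural builders for pacemaker
    geometries (1D automatic-cell chains, an insulated pacemaker with a
    Purkinje exit path, an idealized sheet, and a directly coupled block),
    pseudo-ECG computation from the tissue voltage field, and action-potential
    analysis utilities (upstroke detection, cycle lengths, automaticity
    classification and threshold search, first-pacing time).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
SystemRequirements: C++17
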