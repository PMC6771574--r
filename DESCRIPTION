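Package: littplan
Title: Automated Trajectory Planning for Laser Interstitial Thermal Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constraint-based stereotactic trajectory planning for laser
    interstitial thermal therapy (LITT) of the mesial temporal lobe. Given a
    labelled brain volume (whole-brain parcellation) and a vasculature mask,
    the planner searches an occipito-temporal entry region for an avascular
    path to an anatomically parameterised amygdala target, scores candidate
    trajectories by a normalised vessel-distance risk metric sampled at 128
    nodes, models the thermal ablation cavity as a uniform-diameter capsule
    along the distal trajectory, and reports per-structure ablation volumes
    and percentages. A seeded phantom generator produces synthetic head
    scenes so the whole pipeline runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
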