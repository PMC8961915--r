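Package: kneelkin
Title: Kneeling Knee Kinematics and Contact Points from Single-Plane Fluoroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of tibiofemoral kinematics during deep
    kneeling (Seiza). Generates synthetic knees (parametric bone meshes with
    analytic landmarks, ground-truth six degree-of-freedom trajectories, and
    perspective silhouette projections emulating lateral fluoroscopy),
    recovers bone poses by iterative 2D/3D silhouette registration, converts
    poses to Grood-Suntay joint-coordinate-system kinematics resampled on a
    5-degree flexion grid with B-spline smoothing, estimates medial and
    lateral contact points from mesh proximity on the tibial plateau, and
    compares the flexion and extension phases with paired t-tests and a
    linear mixed model for repeated measures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    lme4,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
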