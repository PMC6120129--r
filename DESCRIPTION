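Package: mstbackbone
Title: Structural Connectome Backbone Analysis of the Rat Brain
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A pipeline for minimum-spanning-tree (MST) backbone analysis of
    structural brain networks reconstructed from diffusion MRI, modeled on
    post-stroke rat connectome studies. Provides a synthetic diffusion phantom
    generator (atlas label volumes, bundle tensor fields, forward-simulated
    diffusion-weighted signal, network cohorts and behavioral scores),
    log-linear diffusion tensor fitting with FA/RD/AD maps and tissue
    summaries, deterministic principal-direction streamline tractography,
    atlas-based weighted network construction with group prevalence matrices,
    Prim-Jarnik MST extraction on inverse-weight costs with nodal and network
    tree metrics (betweenness centrality, strength, leaf number, diameter,
    eccentricity, kappa), and univariable regression of backbone metrics
    against lesion size and sensorimotor deficit scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
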