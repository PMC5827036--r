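Package: uptakesim
Title: Agent-Based Micro-Pharmacological Simulation of Targeted Ligand
    Uptake in Heterogeneous Tumor Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates discrete targeted-ligand molecules diffusing through
    an explicit two-dimensional tumor-tissue topology, binding to per-cell
    membrane pseudo-receptors with probabilistic affinity, and being
    internalized by receptor-mediated endocytosis. Provides a seeded,
    reproducible Brownian-dynamics engine with vascular release schedules
    (bolus-like fast release or continuous slow release), tissue generation
    and import from segmentation masks, one-phase association and Hill /
    log-dose specific-binding curve fitting, and single-cell and
    single-receptor saturation analyses for comparing ligand diffusivity,
    binding affinity, dose, and release scheme.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    optparse,
    yaml
Config/testthat/edition: 3
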