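Package: sumdtoy
Title: Supervised Molecular Dynamics on Toy Receptor-Ligand Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale simulator and analysis toolkit for supervised
    molecular dynamics (SuMD) adaptive sampling of ligand-receptor
    recognition. Provides analytic Gaussian-well/barrier toy energy
    landscapes with preset binder, allosteric-modulator and diffusive
    scenarios, a BAOAB Langevin integrator, the slope-supervised
    (tabu-like) windowed sampling engine with arrival-triggered classical
    dynamics, recognition-energy-landscape and metastable-state trajectory
    analyses, residence-weighted binding-path summaries, well-tempered
    metadynamics with free-energy reconstruction on one or two collective
    variables, and Eyring transition-state arithmetic linking unbinding
    rate changes to transition-state free-energy shifts. Trajectories,
    supervision logs, hills and free-energy surfaces are exchanged in
    plain-text XYZ, CSV, PDB, YAML/JSON and PLUMED-style HILLS formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
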