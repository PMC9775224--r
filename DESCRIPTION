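Package: protlink
Title: Protonation Linkage Analysis for Constant-pH Molecular Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Post-processing toolkit for constant-pH molecular dynamics
    (CpHMD) output. Computes per-pH titration statistics from binary
    proton-occupancy trajectories, fluctuation-derived titration slopes,
    Hill fits of site titration curves, and pH-dependent relative
    association free energies by analytic integration of thermodynamically
    anchored cubic Hermite splines (Wyman-Tanford linkage), with exact
    per-site decomposition and bootstrap error envelopes. Also provides
    proton-occupancy Pearson correlation networks and exchange-time
    analysis, Gaussian-kernel ionic concentration grids with OpenDX
    import/export and Boltzmann-relation concentration maps, structural
    analyses (Kabsch superposition, RMSD, dissociation filtering,
    Shrake-Rupley solvent-accessible surface area, contact areas,
    interface dihedrals, decoupled-fit principal component analysis and
    free-energy landscapes), and an exactly solvable coupled-site
    titration model (binding polynomials by state enumeration plus a
    Metropolis occupancy sampler) that serves as a reference oracle for
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    minpack.lm,
    yaml,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
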