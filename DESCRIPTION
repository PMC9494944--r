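Package: pepmem
Title: Peptide-Membrane Adsorption Analysis from Trajectories, Free-Energy
    Surfaces and Dual-Color FCCS
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis of cationic peptide adsorption onto
    zwitterionic lipid bilayers. Computes adsorption free energies by
    Boltzmann inversion of symmetrized number-density profiles from
    molecular-dynamics z-coordinate trajectories, post-processes
    two-dimensional well-tempered metadynamics free-energy surfaces
    (symmetrization, bulk zeroing, minima, convergence), and implements the
    dual-color fluorescence cross-correlation spectroscopy (FCCS) binding
    analysis: multi-tau correlation of photon-count traces, diffusion-model
    amplitude fits, effective detection volumes, bound-peptide and
    free-concentration bookkeeping, and Langmuir isotherm fits for the
    dissociation constant. Includes seeded synthetic-data generators with
    known ground truth: Metropolis sampling of membrane-like potentials of
    mean force, toy contact trajectories, noisy free-energy grids, and
    Brownian-dynamics confocal photon traces of vesicle-peptide mixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
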