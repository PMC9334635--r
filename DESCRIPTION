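Package: cavitydemix
Title: Entropy-Driven Demixing of DNA in Elliptical Nanocavities
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models and analyzes the spatial organization of DNA molecules
    confined in shallow elliptical nanofluidic cavities. Provides a
    ground-state-dominance mean-field solver for the concentration profile of
    a confined chain, boundary-integrated wall potentials with exponential or
    WCA kernels, Boltzmann prediction and cosine-similarity fitting of
    plasmid position distributions, overdamped Brownian-dynamics simulation
    on empirical free-energy landscapes, and trajectory statistics (order
    parameter, pole-swap and pole-dwell times, per-axis mean-squared
    displacement exponents, crowding density profiles), together with
    synthetic-data generators (two-particle Langevin trajectories,
    Boltzmann-sampled positions, rendered fluorescence movies) that stand in
    for the microscope.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
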