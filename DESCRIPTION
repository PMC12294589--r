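Package: fklpi
Title: Feynman-Kleinert Linearized Path Integral Simulations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Approximate quantum time-correlation functions by the classical
    Wigner (linearized path integral) route.  Phase-space points are sampled
    from a semi-analytic Wigner transform of the Boltzmann operator built on
    the Feynman-Kleinert variational effective frequency, then propagated
    classically or with the ensemble-conserving planetary scheme in which
    centroids move on the centroid potential and fluctuation points rotate
    around them.  Includes model potentials, Monte Carlo phase-space
    sampling with a barrier branch, correlation functions and spectra,
    quantum correction factors, transport and structure estimators, exact
    one-dimensional grid oracles for validation, and a reproducible run
    workbench with a thin command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
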