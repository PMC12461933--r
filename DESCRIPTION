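Package: idpval
Title: Validation of Intrinsically Disordered Protein Ensembles Against
    SAXS and NMR Observables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes experimental observables from conformational ensembles
    of intrinsically disordered proteins and scores their agreement with
    measured data. From coordinate trajectories it derives small-angle X-ray
    scattering profiles (Debye formula), Guinier and Kratky analyses and
    error-weighted profile fits; backbone amide 15N relaxation times T1, T2
    and heteronuclear NOE via rotational correlation functions, a regularized
    inverse Laplace transform onto a log-spaced timescale grid, spectral
    densities and the Redfield equations; per-residue alpha-helicity by
    Kabsch-Sander hydrogen-bond assignment; directional correlation maps of
    consecutive C-alpha vectors; radius-of-gyration statistics against
    polymer scaling laws; and chemical-shift comparison under combined
    simulation and prediction errors. A synthetic-data module generates
    analytically solvable inputs (isotropic and two-timescale rotational
    diffusion, Gaussian chains, uniform spheres, ideal helices, noisy
    observable tables) so every stage is testable without molecular-dynamics
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    bio3d,
    minpack.lm,
    optparse,
    jsonlite,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
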