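Package: sclcsim
Title: Simulators for Small Cell Lung Cancer Growth, Invasion, Metastasis
    and Multifractal Image Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A suite of deterministic and stochastic simulators for
    mathematical oncology of small cell lung cancer (SCLC): a hypoxia- and
    drug-coupled lattice cellular automaton of tumor growth with
    microenvironment-dependent division, apoptosis, necrosis and lysis; an
    implicit finite-volume reaction-diffusion solver for oxygen and drug
    fields with per-cell uptake; Gompertz tumor growth coupled to a dynamic
    angiogenesis-driven carrying capacity; the acid-mediated invasion
    reaction-diffusion system with a derived single-cell biased random
    walk; an endpoint-constrained organ-redistribution metastasis
    simulation; and multifractal image analysis (similarity and
    box-counting dimensions, Holder exponent alpha-images, f(alpha)
    spectra) with generators for fractal test images.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
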