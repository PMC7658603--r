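Package: celsim
Title: Monte Carlo Simulation of Cherenkov Emission and Cherenkov-Excited
    Luminescence in Layered Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the lateral spread and depth sensitivity of Cherenkov
    emission and Cherenkov-excited luminescence during megavoltage
    radiotherapy beam delivery. Cherenkov photon origins are sampled from
    percentage depth-dose curves with a Frank-Tamm 1/wavelength^2 spectrum
    and propagated through a multilayer skin + adipose + muscle model by
    weighted Monte Carlo random walk (Henyey-Greenstein scattering, implicit
    capture, Russian roulette, Fresnel boundaries). A spherical luminescent
    inclusion converts absorbed excitation light into red-shifted emission,
    and tallies of generated / exited / surface-detected photons quantify
    depth sensitivity. Includes beam-penumbra (FWHM versus depth) analysis,
    spectral tallies, a spectral-overlap ranking of candidate luminescent
    reporter compounds against the in-tissue Cherenkov spectrum, and
    deterministic synthetic fixtures (tissue property tables, Gaussian-band
    compound databases) for fully reproducible testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
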