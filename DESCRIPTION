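Package: celldosim
Title: Monte-Carlo Cellular Microdosimetry for Radioactive Gold Nanoparticles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates energy deposition in the organelles of a spherical
    Chinese hamster ovary (CHO) cell model loaded with radioactive 198Au gold
    nanoparticles. Provides an analytically validated nested-sphere cell
    geometry (nucleus, mitochondria, membrane, nanoparticles) with
    rejection-sampled placement and exact ray-sphere path tracing, a 198Au
    decay source (allowed-shape beta spectrum and discrete gamma lines), a
    condensed-step electron transport surrogate (Bethe collision stopping
    power, CSDA ranges, Highland multiple scattering) with single-interaction
    photon attenuation, and organelle-resolved energy-deposit scoring
    including relative enhancement for nucleus-targeted nanoparticles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
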