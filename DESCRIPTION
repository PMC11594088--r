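Package: gelassay
Title: Hyperelastic Identification, Network Structure and Equilibrium
    Swelling of Biopolymer Hydrogels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative macromolecular analysis of biopolymer hydrogels
    from uniaxial compression cycles and gravimetric/pycnometric swelling
    series. Implements Neo-Hookean and Arruda-Boyce (eight-chain)
    hyperelastic parameter identification with an inverse-Langevin
    approximation certified against a numerical oracle, derivation of
    polymer-network structural parameters (strand and cross-link number
    densities, mesh size, polymer-solvent friction proxy) from fitted shear
    moduli, hysteresis quantification of loading-unloading cycles,
    first-order swelling kinetics, composition algebra for pycnometry-style
    measurements, and a Flory-Rehner equilibrium-swelling solver for the
    polymer-solvent interaction parameter chi. A synthetic-data generator
    with full ground-truth bookkeeping emulates the cyclic-compression and
    swelling protocols for end-to-end parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
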