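Package: dielstab
Title: Dielectric Spectroscopy Analysis of Amorphous Drug-Polymer Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for assessing the physical stability of amorphous
    drug-polymer dispersions from broadband dielectric spectroscopy data.
    Fits the Havriliak-Negami function with a dc-conductivity term to
    dielectric loss spectra, converts fitted relaxation times to
    alpha-relaxation peak times, fits the Vogel-Fulcher-Tammann law to
    relaxation maps and extrapolates glass-transition and isochronal
    temperatures, models glass-transition versus composition with the
    Gordon-Taylor mixing rule (including inversion to estimate residual
    drug solubility), and detects crystallization onset and kinetics from
    the collapse of the dielectric strength.  A seeded synthetic-data
    generator produces ground-truth-labelled spectra, temperature scans
    and isothermal crystallization traces for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    yaml,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
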