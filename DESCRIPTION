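Package: phanox
Title: Forward Carbon-Sulphur-Oxygen Box Model of Phanerozoic Atmospheric Oxygen
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A GEOCARB/COPSE-family biogeochemical box model of the coupled
    Phanerozoic carbon, sulphur and oxygen cycles. Organic-carbon burial is
    inverted from a seawater carbonate delta13C record by isotope mass
    balance, while pyrite and gypsum burial and weathering are computed
    forward from model state (ocean sulphate, organic burial, normalized O2)
    rather than by inverting the delta34S record, which is reserved for
    validation against the model's synthetic delta34S output. The model
    integrates reservoir masses and isotope compositions from 570 Ma to the
    present with a stiff ODE solver and reports atmospheric O2 in percent of
    the atmosphere. Includes time-dependent Earth-system forcings, record
    smoothing and perturbation, sensitivity sweeps (carbon-fractionation
    oxygen feedback strength, delta13C standard-deviation envelopes), a
    diagnostic of the legacy isotope-inverted sulphur scheme, and synthetic
    data generators so that the full analysis runs without external files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    knitr
Config/testthat/edition: 3
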