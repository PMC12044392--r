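Package: iscsim
Title: Red Cell Homeostasis Simulation of the Irreversibly Sickled Cell Life Cycle
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pump-leak model of red blood cell ion and water homeostasis
    coupled to a stochastic oxy/deoxy circulation scheduler, built to
    simulate the circulatory life cycle of irreversibly sickled cells
    (ISCs). Deoxygenation of HbS opens poorly selective PIEZO1 channels
    with randomly varying amplitude in successive venous transits;
    calcium influx activates Gardos (KCNN4) channels, driving KCl and
    water loss toward a hyperdense volume trough, followed by a
    volume-stable pathogenic phase sustained by vigorous sodium pump-leak
    turnover, and terminal rehydration triggered by sodium pump
    inhibition. Fast equilibria (Jacobs-Stewart proton/anion ratio,
    hemoglobin titration and osmotic virial behaviour, zero-current
    membrane potential, magnesium buffering) are re-solved after every
    flux step. Includes phase detection and summary statistics, parameter
    scans, a line-oriented protocol file format, CSV time-series output,
    and figure-style plots.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
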