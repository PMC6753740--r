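Package: proton4d
Title: Quasi-Continuous 4D Dose Simulation for Synchrotron Spot-Scanning
    Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates pencil-beam scanned proton delivery to a moving
    spherical target in a homogeneous water phantom. An analytic beam model
    (Bragg-curve depth dose with range straggling, double-Gaussian lateral
    spread with divergence and multiple-scattering growth) is combined with
    a discrete-event model of synchrotron delivery timing (spill, charge
    capacity and hold time, energy switching, spot verification, gate
    latency buffers) to accumulate 4D dose at the temporal midpoint of each
    spot delivery. Respiratory motion is taken from surrogate breathing
    traces, either loaded from file or synthesized with cycle-to-cycle
    amplitude, period, and baseline irregularity. Amplitude gating,
    maximum-MU layered repainting, and their combination can be swept over
    configurable grids; plan quality is scored with DVH-based metrics
    (V97%, homogeneity index, high-dose spillage) against delivery time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pracma,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
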