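Package: drdifc
Title: Dual-Ratio Diffuse In Vivo Flow Cytometry Simulation and Calibration
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward modeling and calibration tools for dual-ratio (DR)
    diffuse in vivo flow cytometry (DiFC). Includes a voxel-based
    Monte-Carlo photon transport kernel (Henyey-Greenstein scattering,
    Fresnel boundaries, pencil and cone beams) with a semi-infinite
    diffusion-theory closed form, fluorescence Jacobian construction,
    single-distance/single-ratio/dual-ratio measurement algebra, a
    multiplicative coupling-coefficient noise model with a non-cancelable
    component, robust background/noise/peak estimation from detector-current
    time series, autofluorescence and target coefficient fitting, and the
    derived analyses: SNR maps over target position, simulated flow traces,
    maximum-detectable-depth scans, and non-cancelable-noise sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    pracma,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
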