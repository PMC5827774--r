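Package: firestrain
Title: Physiological Heat Strain of Clothed Humans Under Low-Level Thermal Radiation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coupled numerical model of the heat strain experienced by a
    clothed human exposed to low-level thermal radiation. A one-dimensional
    transient conduction-radiation finite-difference solver (Crank-Nicolson)
    spans the three layers of firefighter turnout clothing and the enclosed
    air gap between the thermal liner and the skin, with Beer-Lambert
    in-depth absorption of the incident radiation and Rayleigh-gated natural
    convection in the gap. The clothing solver is coupled at every time step
    to an 81-node (20 segments x 4 tissue layers + central blood)
    thermoregulation model with active control of vasodilatation,
    vasoconstriction, sweating and shivering. Heat-strain endpoints (safe
    exposure time against a 38.5 degC core threshold, effective cooling
    time, dangerous time zone, 44 degC skin-burn flag) are computed from the
    simulated core and mean skin temperature traces, and parametric sweeps
    over radiant intensity and air-gap size are provided, together with a
    bench-top mode that drives the body model directly from a measured or
    synthetic skin heat-flux trace.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
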