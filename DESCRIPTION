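Package: irtrad
Title: Independent Reaction Times Simulation of Water Radiolysis Track
    Chemistry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Stochastic simulation of the nonhomogeneous chemical stage of
    water radiolysis at 25 C using the independent reaction times (IRT)
    method. Generates synthetic 1-ps track configurations (isolated spurs
    for low-LET gamma-like irradiation, dense short tracks for tritium
    beta electrons), propagates diffusion-controlled radical chemistry
    including azide and dissolved-oxygen scavengers, and computes
    time-dependent and escape radiation chemical yields (G-values) of
    molecular hydrogen and the other radiolytic species. A step-by-step
    Brownian-dynamics simulator for small clusters is included as an
    independent validation oracle for the IRT engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
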