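Package: rhizoconduct
Title: Soil-Phosphorus-Dependent Maize Root Architecture and Root System
    Conductance Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic functional-structural simulation of young Zea mays
    plants (root system, stem and leaves) parameterized per soil-phosphorus
    treatment, coupled to a xylem hydraulic-architecture solver on the
    segmented plant network. Computes root system conductance (Krs), the
    standard uptake fraction (SUF), per-segment radial and axial water flows
    and xylem potentials; fits negative-exponential organ elongation curves;
    fits and applies linear and capped-linear phosphorus dose-response
    functions for axial root radius, crown-root elongation and leaf
    elongation; reads and writes RSML root traces; and generates synthetic
    rhizotron-style data with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    xml2,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
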