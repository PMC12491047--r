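Package: aquadeficit
Title: Deficit-Irrigation Optimization for Drip-Irrigated Maize
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A water-driven maize growth simulator (AquaCrop-style canopy,
    soil-water bucket and normalized-water-productivity biomass), FAO-56
    Penman-Monteith reference evapotranspiration and a synthetic arid-site
    weather generator, extended FAST (EFAST) global sensitivity screening,
    a dual physics-informed neural surrogate constrained by a soil-water
    balance equation and a multiplicative crop water production function,
    dynamic reconstruction (low-rank trajectory features plus an adaptive
    residual-weight and parameter-diffusion mechanism), and a bilevel
    CMA-ES/genetic-algorithm optimizer that allocates a fixed seasonal
    irrigation quota across twelve drip events to maximize yield and
    water-use efficiency.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
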