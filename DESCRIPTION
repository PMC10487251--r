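Package: tacbake
Title: Two-Level Modelling of Total Antioxidant Capacity Kinetics in Baked Goods
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the evolution of total antioxidant capacity (TP, ORAC,
    FRAP assays) of wheat and rye biscuits during baking with a
    phenomenological double-exponential curve combining thermal degradation
    of native antioxidants and de novo formation of Maillard reaction
    products. Curve parameters are estimated per variety-by-temperature
    setting with a hierarchical Bayesian model (JAGS), and a second-level
    support-vector-regression surrogate with an exponential (Laplacian)
    kernel predicts those parameters from grain type, protein, fiber and
    baking temperature, enabling curve prediction at unobserved conditions
    and local one-at-a-time sensitivity analysis. Includes a seeded
    synthetic-data generator for simulation studies and CSV/YAML/JSON
    interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    rjags,
    coda,
    kernlab,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
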