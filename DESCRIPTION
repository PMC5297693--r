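Package: uprswitch
Title: Bistable Life-and-Death Decision Model of the Unfolded Protein Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A four-variable ordinary differential equation model of the
    endoplasmic-reticulum stress response in which the PERK and IRE-1 sensor
    branches drive lumped autophagy and apoptosis inducers coupled by a
    double-negative feedback loop. Provides stiff integration of stress
    protocols (step stress, sensor knockdowns, stressor wash-out),
    stability-annotated signal-response curves with saddle-node fold
    localisation and reversibility classification, qualitative-constraint
    parameter calibration, phenotype calling (survival, death, delayed death)
    from timing features, and a generator of noisy densitometry-style marker
    time courses for validating the phenotype pipeline. Parameter sets can be
    exchanged as YAML configuration or XPP .ode files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
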