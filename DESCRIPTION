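Package: sv2akin
Title: Joint Kinetic Modelling of SV2A Tracer Displacement and Drug Brain Entry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying how fast a drug enters brain tissue from
    paired positron emission tomography (PET) scans in which the drug competes
    with a radiotracer for a common binding site. Implements a nonlinear
    tracer-drug competition compartment model for the synaptic vesicle protein
    2A (SV2A) tracer and the antiseizure drugs levetiracetam and brivaracetam:
    forward simulation of tissue states and target occupancy, joint weighted
    nonlinear least-squares fitting of displacement and post-dose scans,
    nested-model F tests, sensitivity scans over fixed constants, a
    conservative grid-search lower bound on the drug brain-entry-rate ratio,
    and a synthetic-study generator covering tracer bolus-plus-infusion input,
    drug infusion pharmacokinetics and count-statistics noise.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
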