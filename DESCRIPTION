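Package: dntsim
Title: Discrete-Event Simulation of the Intra-Hospital Thrombolysis Pathway
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discrete-event simulation of the intra-hospital treatment process
    for acute ischemic stroke patients receiving thrombolysis (tPA), built to
    study door-to-needle time (DNT) at urban and rural hospitals. Site
    treatment processes are modelled as stochastic activity networks with
    parametric duration distributions, non-homogeneous Poisson patient
    arrivals, separate pathways for ambulance (EMS) and private-vehicle
    arrivals, and regular versus out-of-hours resource variants. Five
    process-improvement scenarios (stretcher-to-imaging, bolus in the imaging
    area, EMS pre-registration, and 35% reductions of treatment-decision and
    tPA-preparation times) are expressed as pure transformations of a site
    configuration and can be combined. Outcome machinery covers pooled
    median/IQR/90th-percentile DNT, percentage reductions with bootstrap
    confidence intervals, Mann-Whitney and chi-square verification tests,
    replication-count analysis, and one-at-a-time sensitivity sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
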