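Package: kneelax
Title: Soft-Tissue Balancing Sensitivity Analysis for Bicruciate-Retaining Knee Arthroplasty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A quasistatic rigid-body model of the tibiofemoral joint with
    multi-bundle nonlinear ligament springs, frictionless articular contact and
    Grood-Suntay joint coordinates, used to simulate intraoperative
    anterior-posterior, internal-external and varus-valgus laxity tests across
    flexion. A Taguchi L81(3^40) orthogonal-array design perturbs ligament
    attachment sites, stiffnesses and reference strains; an ANOVA
    relative-importance statistic ranks each parameter's effect on every laxity
    component, selects the most informative laxity examinations, and derives an
    ordered soft-tissue balancing sequence.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
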