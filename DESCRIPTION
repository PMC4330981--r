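Package: aitcea
Title: Cost-Utility Modelling of Allergen Immunotherapy for Grass-Pollen
    Rhinoconjunctivitis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A nine-year annual-cycle Markov cohort model comparing
    sublingual 5-grass tablet immunotherapy, a subcutaneous allergoid mix
    and symptomatic treatment for seasonal grass-pollen allergic
    rhinoconjunctivitis from the German payer perspective. Provides
    half-cycle-corrected cohort traces, component-wise cost and QALY
    accumulation with discounting, incremental cost-effectiveness ratios
    and net monetary benefit, deterministic (tornado) and probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves,
    declarative scenario analyses, an anchored indirect treatment
    comparison on standardized mean differences with fixed-effect
    inverse-variance pooling, and calibration routines that recover the
    utility slope, resource-use counts and productivity savings from
    published component totals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
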