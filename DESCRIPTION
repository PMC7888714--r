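Package: wbpleth
Title: Whole-Body Plethysmography Analysis, Apnea Scoring and Craniofacial Morphometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Breath-by-breath analysis of whole-body barometric plethysmography
    recordings in rodents: breath segmentation from chamber-pressure traces,
    tidal volume via the Drorbaugh-Fenn barometric correction, minute
    ventilation, oxygen consumption by pull-mode indirect calorimetry
    (Lighton equation), rule-based scoring of spontaneous apneas, sighs and
    post-sigh apneas, and protocol-epoch summaries across normoxia, hypoxia
    and hyperoxia. Includes landmark-based craniofacial morphometrics with
    triplicate-rater reliability (ICC), a cohort statistics layer (Student's
    t, one-way ANOVA, two-way repeated-measures ANOVA with Holm-Sidak post
    tests, metabolite screening), and seeded synthetic-data generators that
    emulate eupneic mouse breathing, inserted respiratory events, the
    biphasic hypoxic ventilatory response, gas-fraction traces and jittered
    landmark replicates with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
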