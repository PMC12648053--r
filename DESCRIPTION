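Package: ckdcea
Title: Cost-Utility Markov Model for Protein-Restricted Diets in Advanced Chronic Kidney Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lifetime Markov cohort model comparing a ketoanalogue-supplemented
    very-low-protein diet (s-VLPD) against a conventional low-protein diet (LPD)
    in chronic kidney disease stages 4-5. Tracks pre-dialysis, dialysis and death
    states at monthly cycles, converts annual probabilities to competing hazards,
    and reports survival, time in state, quality-adjusted life years and itemized
    discounted costs from a healthcare-payer or societal perspective. Includes
    incremental cost-effectiveness comparison with dominance classification,
    one-way deterministic sensitivity analysis (tornado), probabilistic
    sensitivity analysis with cost-effectiveness plane, confidence ellipse and
    acceptability curve, and scenario analyses for a dialysis-mortality benefit
    and partial dietary adherence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
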