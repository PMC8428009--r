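Package: cardiophen
Title: Rule-Based Extraction of Cardiovascular Comorbidities from Clinical Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A transparent, heuristic clinical natural language processing
    engine for phenotyping cardiovascular comorbidities in free-text
    electronic health record notes. Sentences are segmented, tokenized,
    tagged with declarative word classes, and matched against phrase
    patterns; negated findings and family-history mentions are suppressed
    so only the patient's personal history is reported. Ships five
    re-authored comorbidity modules (hypertension, dyslipidemia, diabetes,
    coronary artery disease, non-hemorrhagic stroke/TIA) with multi-level
    diagnostic categories, a two-level evaluation harness (sentence- and
    note-level sensitivity, specificity and positive predictive value with
    exact binomial confidence intervals, corrected variants, and Cohen's
    kappa for inter-adjudicator agreement), and a seeded synthetic-note
    generator that produces labeled corpora so the whole pipeline can be
    exercised without any clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
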