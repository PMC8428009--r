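# cardiophen

Transparent, rule-based extraction of cardiovascular comorbidities from
free-text clinical notes, with the evaluation machinery to validate the
rules against physician-adjudicated gold standards — and a synthetic
labeled-note generator so the whole pipeline can be developed and tested
without touching any clinical data.

## Who this is for

Clinical researchers and EHR phenotyping teams who need to know, per
patient note, whether the clinician documented **hypertension,
dyslipidemia, diabetes, coronary artery disease (CAD), or
non-hemorrhagic stroke/TIA** — including clinically useful sublevels
(type 1 vs type 2 diabetes; MI, STEMI, unstable angina, >50% coronary
stenosis, revascularization; ischemic vs embolic stroke vs TIA) — and
who want every extraction to be traceable to a human-readable rule
rather than a model weight.

## How the engine works

Each comorbidity module is a declarative YAML rule set with two layers:

1. **Word classes** — named sets of semantically interchangeable surface
   terms, e.g. `CAD = {cad, coronary artery disease, coronary heart
   disease, ischemic heart disease}`. Tagging is greedy longest-match
   over lower-cased tokens; any token outside the lexicon becomes the
   reserved `UNKNOWN` class, and numeric tokens become `NUM`.
2. **Phrase patterns** — ordered sequences over word classes with
   optional elements (`NUM?`) and bounded wildcard gaps (`ANY*`), e.g.

   ```
   NUM? STENT ANY* CORONARY   ->   cad.revascularization
   ```

   which fires on "The patient had **2 stents** placed in his **LAD**
   in July 2018". Patterns resolve to numbered outputs and diagnostic
   categories; categories are deduplicated per sentence.

A context filter then suppresses matches that are **negated** ("the
patient has no personal history of CAD") or describe **family, not
personal, history** ("family history of ischemic heart disease"), using
trigger terms scoped to the clause that contains the match. Note-level
flags are the union of surviving sentence-level references; a
subcategory flag always implies its concept flag.

## Evaluation methodology

Against a gold CSV of adjudicated references the package computes, per
concept and per subcategory:

* **sentence level**: sensitivity and PPV over unique
  `(note, sentence, category)` references (specificity is structurally
  NA — sentence-level true negatives are not enumerable);
* **note level**: sensitivity, specificity, and PPV over per-note
  binary presence, with `TP + FP + FN + TN = corpus size`;
* **corrected variants**: secondary-review corrections reclassify
  system-found, adjudicator-missed true positives from FP to TP
  (`TP' = TP + c`, `FP' = FP - c`), so corrected sensitivity and PPV
  never fall below the originals;
* exact **Clopper–Pearson 95% binomial intervals** for every estimate,
  reported in percent as `estimate (low–high)`;
* **Cohen's kappa** between two adjudicators' note-level labels,
  `kappa = (p_o - p_e) / (1 - p_e)`.

## Worked example

```r
library(cardiophen)

ann <- extract_sentence(
  "Mr. Smith has a history of CAD s/p MI in 2018 requiring 2 stents to his LAD",
  "cad")
ann$categories
#> [1] "cad.unspecified"       "cad.mi"                "cad.revascularization"

extract_sentence("The patient has no personal history of CAD", "cad")$categories
#> character(0)

metric_with_ci(29, 29, "sensitivity")
#> <metric_result> sensitivity: 100 (88.1-100)  [29/29]

cohens_kappa(c(1, 1, 0, 0), c(1, 0, 0, 0))
#> [1] 0.5
```

The first sentence carries three layers of diagnostic information — a
general CAD reference, a myocardial infarction, and a coronary
revascularization — and the engine reports all three, exactly as a
trained adjudicator would tick three boxes for that sentence. The
negated sentence yields nothing. `metric_with_ci` shows the evaluation
convention: 29 of 29 detected is 100% sensitivity with an exact lower
bound of 88.1%.

End-to-end on synthetic data:

```r
cfg  <- generator_config(n_notes = 200, seed = 42)
corp <- generate_corpus(cfg)            # notes + gold labels
pred <- extract_corpus(corp$notes)      # all five modules
rep  <- evaluate_run(corp$gold, pred)
print(rep)                              # per-concept metric table
```

A command-line surface (`inst/cli/cardiophen.R`) wraps the same
functions: `extract`, `evaluate`, `kappa`, `simulate`,
`validate-module`. File formats are documented in `inst/FORMATS.md`.

## Limitations

The engine reads documentation, not truth: it cannot detect a
clinician's erroneous assertion, does not resolve hedging ("possible
CAD" counts as positive), temporality, or cross-sentence coreference,
and the shipped modules are representative re-authored rule sets —
smaller than a production lexicon and tuned to favor specificity. See
the methods vignette (`vignettes/cardiophen-methods.Rmd`) for the full
design rationale.
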