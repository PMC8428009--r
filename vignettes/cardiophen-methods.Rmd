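---
title: "Methods: rule-based comorbidity extraction and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based comorbidity extraction and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiophen)
```

# The extraction model

`cardiophen` implements a deliberately transparent pipeline for
phenotyping five cardiovascular comorbidities from free-text notes.
Every positive assertion the system makes can be traced to a specific
phrase pattern firing on specific tokens, which is the property that
makes rule sets auditable and correctable by clinicians — the central
design commitment of this package, chosen over statistical models whose
categorizations cannot be inspected.

The pipeline is a fixed composition:

```
segment -> tokenize -> tag word classes -> match phrase patterns
        -> suppress negation / family history -> resolve categories
```

## Sentence segmentation

Clinical prose is abbreviation-dense, so the segmenter is conservative.
Terminators are `.`, `!`, `?` followed by whitespace, plus line breaks
(which makes one-line section headers such as `History: uncontrolled
hemoglobin A1c` their own sentences). A period never splits when it
closes a protected form (`Mrs.`, `Dr.`, `pt.`, dosing abbreviations
such as `b.i.d.`; the list ships as editable data in
`protected_abbreviations()`), a single capital initial, or a decimal
number. Sentence records carry 0-based half-open character spans into
the note, and the substring at a span is exactly the sentence text, so
every downstream annotation is relocatable in the source document.

## Tokenization and word-class tagging

Tokens split on whitespace and punctuation except for `/`, `-` and
apostrophes inside tokens (`s/p`, `h/o`, `type-2`), `.` inside decimal
numbers, and `%` attached to a number (`>50%` becomes `>` then `50%`).
Punctuation characters survive as one-character tokens because clause
boundaries (`,`, `;`) matter to the context filter. Matching is on
lower-cased normalized tokens throughout: clinical notes mix `CAD` and
`cad` freely, and case carries no diagnostic signal here.

Word classes are matched greedily left-to-right, longest match first,
so `coronary heart disease` is consumed as one three-token class span
rather than partially. Two numerical-choice details are deliberate:

* **Ties** at equal length break by word-class declaration order in the
  module file. Determinism is required for reproducible extraction, and
  declaration order is the one ordering a rule author controls.
* **Collisions** — the same term declared in two word classes of one
  module — are a load-time error rather than a silent priority rule, so
  tagging is guaranteed unambiguous.

Uncovered tokens become single-token spans of the reserved `UNKNOWN`
class; numeric tokens become `NUM`. The single-token convention for
`UNKNOWN` (rather than runs) is this package's choice: pattern-level
`ANY*` gaps express "some words we do not model", so the tag layer can
stay maximally granular.

## Phrase patterns

A pattern is an ordered element sequence over word classes, with `?`
marking an optional element and `ANY*` a gap of zero or more spans that
never crosses a sentence. Gaps are non-greedy, and matches collapse to
one per `(pattern, leftmost start)` — a placement of the same pattern
that shares an end but starts later is the same firing with a leading
optional skipped and is not double-counted. This matters because
evaluation counts unique sentence-level references; double-counted
provenance would silently inflate nothing today but would corrupt any
future per-pattern statistics.

The `>50% coronary stenosis` category needs arithmetic, not just
vocabulary: a `num_ge_50_pct` guard accepts a match only if a `NUM`
token it covers is at least 50 and carries a percent sign. A bare
`A1c`-with-value pattern was deliberately **not** shipped for diabetes:
it would fire on normal values, and where sensitivity and specificity
conflicted, the shipped rules favor specificity. The same principle
shows up as an absorber class in the stroke module: `hemorrhagic
stroke` is declared as a word class that no pattern references, so
longest-match tagging consumes it whole and the bare `stroke` patterns
cannot fire on hemorrhagic events, which are out of scope.

## Negation and family history

The suppression layer is a trigger-and-clause-scope scheme in the
style of classic clinical negation heuristics: transparent, fast, and
editable. A match is suppressed if a negation pre-trigger (`no`,
`denies`, `negative for`, ...) *starts* before the match start within
the same clause, a post-trigger (`ruled out`, `unlikely`) ends after
the match within the clause, or a family trigger (`family history`,
`mother`, ...) starts before it in-clause. Three scoping decisions are
worth recording:

* **Clause scope, not a fixed token window.** Discharge summaries chain
  clauses with commas and conjunctions; "No chest pain, **but known
  CAD**" must keep the CAD finding, and a window of k tokens either
  over- or under-suppresses depending on k.
* **Trigger start (not end) bounds the comparison**, so a trigger may
  overlap the match: "no **history of** CAD" suppresses the match that
  itself begins at "history".
* **Family scope is also clause-level**, so "mother had an MI; pt with
  HTN" keeps the patient's own hypertension.

Hedged mentions ("probable CAD") are counted positive: the package does
not model uncertainty, and this is flagged here rather than hidden.

# The five shipped modules

The modules are representative re-authored rule sets, not reproductions
of any published rule files: smaller, but structurally faithful (the
three multi-level modules each carry at least 10 word classes and 25
patterns, and every subcategory of the taxonomy is covered). Two
taxonomy choices were genuinely open:

* Hypertension and dyslipidemia carry a single `present` subcategory so
  all five concepts share one annotation schema.
* STEMI and MI are sibling subcategories under CAD; a STEMI mention
  does not additionally set the MI flag. The taxonomy lists them as
  separate levels of information, and keeping them disjoint preserves
  the invariant that each subcategory flag traces to its own patterns.
  Consumers who want "any infarction" can union the two flags.

Patterns may in principle reference literal words only via word
classes; the DSL keeps a single referencing mechanism because every
additional pattern primitive is one more thing an auditor must learn.

# The evaluation layer

Sentence-level analysis counts unique `(note, sentence, category)`
references; note-level analysis counts per-note binary presence.
Sentence-level specificity is structurally NA — there is no enumerable
population of "negative sentences" once a sentence can host several
categories — and the report prints NA rather than inventing a TN count.

Confidence intervals are exact Clopper–Pearson, computed from beta
quantiles, two-sided at 95%. The method was validated against the two
interval bounds that are fully recoverable from published counts alone
(a 29/29 sensitivity has lower bound 88.1%; a 132/132 specificity has
lower bound 97.2%), and coverage is verified by simulation in the test
suite. Estimates display in percent rounded half-even to one decimal;
full precision is kept internally.

Corrected metrics reclassify system-found, adjudicator-missed true
positives from FP to TP with all other counts fixed (`TP' = TP + c`,
`FP' = FP - c`; at note level TN is unchanged, so corrected specificity
is `TN / (TN + FP - c)`). This bookkeeping is the unique choice under
which corrected sensitivity and PPV can never fall below the originals,
which the test suite verifies exhaustively for all counts up to 50.

Dual-adjudicator gold tables are merged by union, with every reference
not logged by both adjudicators emitted as an explicit conflict list
(and a distinct CLI exit code) rather than silently resolved; the
intended workflow is that conflicts go back to a joint review and a
merged table is re-supplied. Cohen's kappa over note-level flags is
computed from the raters' marginals; two identical constant labelings
return 1, and kappa is cross-checked against an independent
implementation in the tests.

# The synthetic-note generator

The generator exists so that extraction and evaluation are testable
with zero clinical data. Its defaults are the package's study
conditions and are not tuning knobs:

| Parameter | Default | Rationale |
|---|---|---|
| `n_notes` | 200 | the size of a realistic held-out validation set |
| `note_type_mix` | 0.7 outpatient / 0.3 discharge | a predominately outpatient mix |
| concept prevalence | 0.41 / 0.34 / 0.145 / 0.27 / 0.205 | note-level positive rates of the five concepts in a 200-note cardiovascular validation corpus, spread over subcategories |
| `mentions_per_positive` | 1–4 | matches sentence-to-note reference ratios of roughly 2.6–4 |
| `negation_rate` | 0.2 | negated mentions are common enough to matter |
| `family_history_rate` | 0.2 | one family-history distractor in a fifth of notes |
| `distractor_sentences_per_note` | 3 | keeps diagnostic sentences a minority of each note |

Notes are assembled one sentence per line from a template bank (terms
plus slotted sentence templates per category, negation and
family-history renderings, neutral distractors), shuffled, with a
note-type header first. Gold records are emitted for every planted
positive at sentence and note level; negated and family renderings are
explicitly *not* gold. A single seeded RNG stream drives all sampling
in documented order, and every branch consumes the same number of
variates, so toggling one rate (e.g. negation 0 to 1) changes renderings
without reshuffling everything else, and identical config plus seed is
byte-identical output.

`plant_errors` induces an exactly known confusion: false negatives are
out-of-lexicon paraphrases ("home pressure readings above goal") added
to gold in previously concept-negative notes; false positives are
trigger-adjacent traps the engine genuinely matches but a physician
would not log ("white-coat hypertension was suspected", "screening for
diabetes will be performed"). Each planted item lands in its own
previously-negative note, so the per-concept confusion deltas equal the
planted counts and the manifest is a complete oracle for the evaluation
harness.

What the generator does **not** emulate — and what passing tests
therefore do not show about real notes: misspellings, truncated or
telegraphic phrasing, templated EHR boilerplate, copy-forward
duplication, realistic note-length distributions, hedged or temporally
qualified mentions, and above all the open-ended phrasing variability
of real clinicians. Perfect recovery on the synthetic corpus
demonstrates the *internal consistency* of engine, rules, and
evaluation (the generator only emits lexicon-covered phrasings); it is
not a claim about field performance.

# Problem sizes and runtime choices

The test suite exercises: the full template bank (every rendering
against all five modules), a 200-note planted-error corpus checked
exactly against its manifest, a 500-note error-free corpus for the
perfect-recovery property, 10,000 notes for prevalence recovery
(generation only), 10,000-draw coverage simulations at three binomial
settings, and exhaustive corrected-metric monotonicity to counts of 50.
These sizes were chosen to make the checked properties sharp (multiple
expected positives per subcategory; standard errors small enough that
a 3-SE prevalence band is meaningful) while keeping the whole suite in
a few minutes on one CPU.

# Degenerate inputs

Empty note text yields zero sentences and all-false flags; a
whitespace-only sentence yields zero tokens; an empty corpus evaluates
to an all-TN report; a zero-denominator metric is reported "not
estimable" rather than NaN; a correction that does not correspond to a
counted false positive is an error, as is a gold or prediction note id
outside the declared universe.

# Known limitations

The engine asserts what clinicians wrote, not what is true; it cannot
detect erroneous documentation. Uncertainty, temporality ("resolved"),
experiencer beyond family triggers, cross-sentence coreference, and
spelling correction are out of scope. The shipped lexicons are
illustrative-scale; production use requires growing the word classes
and patterns against a local corpus, which the YAML DSL and
`validate-module` are designed to make routine.
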