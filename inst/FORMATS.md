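# File formats

All files are UTF-8. CSV files follow RFC 4180 with a mandatory header
row; JSONL files carry one JSON object per line.

## Notes

JSONL (preferred): `{"note_id": "...", "text": "...", "note_type":
"outpatient" | "discharge_summary" | "other"}` per line. CSV with the
same three columns, or a directory of `.txt` files (filename stem =
`note_id`, `note_type = "other"`), are equivalent.

`note_id` must be non-empty and unique within a corpus; `text` may be
empty (a note with no sentences).

## Module definition (rule DSL)

One YAML document per module:

```yaml
meta: {name: cad, version: "1.0"}
concept: cad                      # one of the five concepts
wordclasses:
  CAD: [cad, coronary artery disease, ...]
  ...
patterns:
  - id: cad_history               # unique per module
    output: 2                     # unique integer per module
    category: cad.unspecified     # concept.subcategory
    seq: HISTORY ANY* CAD         # element string
    guard: num_ge_50_pct          # optional numeric guard
```

`seq` elements: a word-class name (required), `NAME?` (optional),
`ANY*` (gap of zero or more spans, bounded by the sentence). `UNKNOWN`
and `NUM` are reserved classes: `UNKNOWN` covers any token outside the
lexicon; `NUM` tags numeric tokens and may be referenced in patterns.
No term may appear in two word classes of the same module.

## Context lexicon

YAML with four non-empty term lists: `negation_pre_triggers`,
`negation_post_triggers`, `family_triggers`, `clause_boundaries`.

## Annotations

JSONL (debug level): `{"note_id", "sentence_index", "char_span":
[start, end), "pattern_id", "output_id", "category"}`. Flat CSV for
review: `note_id, concept, subcategory, sentence_index, char_start,
char_end, pattern_id`. Character offsets are 0-based half-open into the
note text; sentence indices are 0-based.

## Gold standard

CSV: `note_id, adjudicator_id, concept, subcategory, sentence_index`.
`sentence_index` blank for note-level-only rows. Sentence indices must
come from the same segmentation the engine applies (the evaluate
command re-segments the notes itself to guarantee this).

## Corrections

CSV: `note_id, concept, subcategory, sentence_index, confirmed`.
`confirmed = true` marks a system-found, adjudicator-missed item as
truly positive on secondary review; each confirmed row must correspond
to a counted false positive.

## Evaluation report

JSON with `metrics` (long format: target, level, metric, corrected,
estimate, ci_low, ci_high, numerator, denominator, estimable), `counts`
(confusion counts per target/level/variant), `conflicts`, and
`universe_size`; plus an optional rendered text table (Original /
Corrected columns for sensitivity, specificity, PPV at note and
sentence level).

## Error manifest

JSON array of planted items: `note_id, sentence_index, concept,
subcategory, kind` with `kind` = `"fn"` (gold-positive paraphrase the
engine misses) or `"fp"` (trap phrasing the engine flags but gold
excludes).
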