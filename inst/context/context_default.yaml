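# Default context lexicon: negation and family-history triggers with
# clause-boundary scoping. Edit or replace via --context / the `context`
# argument; all matching is on lower-cased normalized tokens.
negation_pre_triggers:
  - "no"
  - "not"
  - "without"
  - "denies"
  - "denied"
  - "negative for"
  - "no history of"
  - "no hx of"
  - "no h/o"
  - "no personal history of"
  - "no known history of"
  - "no evidence of"
  - "no known"
  - "never had"
  - "free of"
negation_post_triggers:
  - "ruled out"
  - "was ruled out"
  - "is ruled out"
  - "unlikely"
  - "not present"
  - "is absent"
family_triggers:
  - "family history"
  - "family hx"
  - "fh"
  - "fhx"
  - "mother"
  - "father"
  - "mother's"
  - "father's"
  - "brother"
  - "sister"
  - "grandmother"
  - "grandfather"
  - "aunt"
  - "uncle"
  - "son"
  - "daughter"
  - "maternal"
  - "paternal"
  - "parents"
clause_boundaries:
  - "but"
  - "however"
  - "although"
  - "though"
  - "whereas"
  - "except"
  - ";"
  - ","
  - ":"
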