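# Dyslipidemia module: single "present" category. Named diagnoses live in
# LIPID_DX ("elevated cholesterol" is a term there and wins the
# longest-match over ELEVATED + CHOL); other lipid-fraction language is
# captured compositionally.
meta:
  name: dyslipidemia
  version: "1.0"
concept: dyslipidemia
wordclasses:
  LIPID_DX:
    - dyslipidemia
    - hyperlipidemia
    - hld
    - hypercholesterolemia
    - hypertriglyceridemia
    - mixed hyperlipidemia
    - elevated cholesterol
    - high cholesterol
    - elevated lipids
    - lipid disorder
  CHOL:
    - cholesterol
    - ldl
    - lipids
    - lipid panel
    - triglycerides
    - non-hdl
  ELEVATED:
    - elevated
    - high
    - uncontrolled
    - borderline high
  HISTORY:
    - history of
    - hx of
    - h/o
    - known
    - longstanding
    - past medical history of
  DIAGNOSIS:
    - diagnosis of
    - diagnosed with
  STATIN:
    - atorvastatin
    - simvastatin
    - rosuvastatin
    - pravastatin
    - statin
  MED_CONTEXT:
    - "on"
    - treated with
    - takes
    - taking
    - started on
patterns:
  - id: lipid_mention
    output: 1
    category: dyslipidemia.present
    seq: LIPID_DX
  - id: lipid_history
    output: 2
    category: dyslipidemia.present
    seq: HISTORY ANY* LIPID_DX
  - id: lipid_diagnosis
    output: 3
    category: dyslipidemia.present
    seq: DIAGNOSIS ANY* LIPID_DX
  - id: lipid_elevated_fraction
    output: 4
    category: dyslipidemia.present
    seq: ELEVATED CHOL
  - id: lipid_fraction_elevated
    output: 5
    category: dyslipidemia.present
    seq: CHOL ANY* ELEVATED
  - id: lipid_statin_for_chol
    output: 6
    category: dyslipidemia.present
    seq: MED_CONTEXT STATIN ANY* CHOL
  - id: lipid_statin_for_dx
    output: 7
    category: dyslipidemia.present
    seq: MED_CONTEXT STATIN ANY* LIPID_DX
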