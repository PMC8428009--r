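# Hypertension module: single "present" category. Surface variants of the
# diagnosis live in HTN; descriptive blood-pressure language is captured
# compositionally (ELEVATED + BP in either order).
meta:
  name: hypertension
  version: "1.0"
concept: hypertension
wordclasses:
  HTN:
    - hypertension
    - htn
    - high blood pressure
    - elevated blood pressure
    - hypertensive
    - essential hypertension
    - chronic hypertension
    - systemic hypertension
    - hypertensive urgency
    - hypertensive emergency
    - hypertensive crisis
  BP:
    - blood pressure
    - bp
    - blood pressures
    - pressures
  ELEVATED:
    - elevated
    - uncontrolled
    - poorly controlled
    - suboptimally controlled
    - labile
  HISTORY:
    - history of
    - hx of
    - h/o
    - known
    - longstanding
    - long-standing
    - prior history of
    - past medical history of
  DIAGNOSIS:
    - diagnosis of
    - diagnosed with
    - carries a diagnosis of
  MED_CONTEXT:
    - "on"
    - treated with
    - managed with
    - takes
    - taking
    - started on
    - continued on
  ANTIHYPERTENSIVE:
    - lisinopril
    - amlodipine
    - losartan
    - hydrochlorothiazide
    - hctz
    - chlorthalidone
patterns:
  - id: htn_mention
    output: 1
    category: hypertension.present
    seq: HTN
  - id: htn_history
    output: 2
    category: hypertension.present
    seq: HISTORY ANY* HTN
  - id: htn_diagnosis
    output: 3
    category: hypertension.present
    seq: DIAGNOSIS ANY* HTN
  - id: htn_elevated_bp
    output: 4
    category: hypertension.present
    seq: ELEVATED ANY* BP
  - id: htn_bp_elevated
    output: 5
    category: hypertension.present
    seq: BP ANY* ELEVATED
  - id: htn_med_for_bp
    output: 6
    category: hypertension.present
    seq: MED_CONTEXT ANTIHYPERTENSIVE ANY* BP
  - id: htn_med_for_htn
    output: 7
    category: hypertension.present
    seq: MED_CONTEXT ANTIHYPERTENSIVE ANY* HTN
  - id: htn_history_elevated_bp
    output: 8
    category: hypertension.present
    seq: HISTORY ANY* ELEVATED ANY* BP
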