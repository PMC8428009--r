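# Diabetes module: three categories (type 1, type 2, unspecified type).
# Typed phrasings are full multi-word terms so longest-match tagging keeps
# "type 2 diabetes" out of the bare DM class; glycemic-control language
# (A1c, glucose) is captured compositionally and resolves to the
# unspecified category.
meta:
  name: diabetes
  version: "1.0"
concept: diabetes
wordclasses:
  DM1:
    - type 1 diabetes
    - type 1 diabetes mellitus
    - type i diabetes
    - type i diabetes mellitus
    - t1dm
    - dm1
    - diabetes mellitus type 1
    - iddm
    - insulin dependent diabetes
    - insulin-dependent diabetes
    - juvenile diabetes
  DM2:
    - type 2 diabetes
    - type 2 diabetes mellitus
    - type ii diabetes
    - type ii diabetes mellitus
    - t2dm
    - dm2
    - diabetes mellitus type 2
    - niddm
    - non-insulin dependent diabetes
    - adult onset diabetes
    - adult-onset diabetes
  DM:
    - diabetes
    - diabetes mellitus
    - dm
    - diabetic
  DM_COMPL:
    - diabetic retinopathy
    - diabetic neuropathy
    - diabetic nephropathy
    - diabetic foot ulcer
    - diabetic ketoacidosis
    - dka
  A1C:
    - hemoglobin a1c
    - hba1c
    - a1c
    - hgba1c
    - glycated hemoglobin
  GLUCOSE:
    - glucose
    - blood sugar
    - blood sugars
    - sugars
    - glycemic control
    - fingersticks
  ELEVATED:
    - elevated
    - uncontrolled
    - poorly controlled
    - high
    - worsening
    - suboptimal
  INSULIN:
    - insulin
    - lantus
    - glargine
    - lispro
  DM_MED:
    - metformin
    - glipizide
    - glyburide
    - sitagliptin
    - empagliflozin
    - liraglutide
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
    - carries a diagnosis of
  MED_CONTEXT:
    - "on"
    - treated with
    - managed with
    - takes
    - taking
    - started on
    - requiring
patterns:
  # --- type 1 ---
  - id: dm1_mention
    output: 1
    category: diabetes.type1
    seq: DM1
  - id: dm1_history
    output: 2
    category: diabetes.type1
    seq: HISTORY ANY* DM1
  - id: dm1_diagnosis
    output: 3
    category: diabetes.type1
    seq: DIAGNOSIS ANY* DM1
  - id: dm1_on_insulin
    output: 4
    category: diabetes.type1
    seq: DM1 ANY* INSULIN
  # --- type 2 ---
  - id: dm2_mention
    output: 10
    category: diabetes.type2
    seq: DM2
  - id: dm2_history
    output: 11
    category: diabetes.type2
    seq: HISTORY ANY* DM2
  - id: dm2_diagnosis
    output: 12
    category: diabetes.type2
    seq: DIAGNOSIS ANY* DM2
  - id: dm2_on_med
    output: 13
    category: diabetes.type2
    seq: DM2 ANY* MED_CONTEXT ANY* DM_MED
  - id: dm2_med_for
    output: 14
    category: diabetes.type2
    seq: MED_CONTEXT DM_MED ANY* DM2
  # --- unspecified type ---
  - id: dm_mention
    output: 20
    category: diabetes.unspecified
    seq: DM
  - id: dm_history
    output: 21
    category: diabetes.unspecified
    seq: HISTORY ANY* DM
  - id: dm_diagnosis
    output: 22
    category: diabetes.unspecified
    seq: DIAGNOSIS ANY* DM
  - id: dm_complication
    output: 23
    category: diabetes.unspecified
    seq: DM_COMPL
  - id: dm_elevated_a1c
    output: 24
    category: diabetes.unspecified
    seq: ELEVATED ANY* A1C
  - id: dm_a1c_elevated
    output: 25
    category: diabetes.unspecified
    seq: A1C ANY* ELEVATED
  - id: dm_elevated_glucose
    output: 27
    category: diabetes.unspecified
    seq: ELEVATED GLUCOSE
  - id: dm_glucose_elevated
    output: 28
    category: diabetes.unspecified
    seq: GLUCOSE ANY* ELEVATED
  - id: dm_on_insulin
    output: 29
    category: diabetes.unspecified
    seq: DM ANY* INSULIN
  - id: dm_insulin_for
    output: 30
    category: diabetes.unspecified
    seq: MED_CONTEXT INSULIN ANY* DM
  - id: dm_med_for
    output: 31
    category: diabetes.unspecified
    seq: MED_CONTEXT DM_MED ANY* DM
  - id: dm_on_med
    output: 32
    category: diabetes.unspecified
    seq: DM ANY* MED_CONTEXT ANY* DM_MED
  - id: dm_insulin_requiring
    output: 33
    category: diabetes.unspecified
    seq: MED_CONTEXT INSULIN ANY* GLUCOSE
  - id: dm_history_elevated_a1c
    output: 34
    category: diabetes.unspecified
    seq: HISTORY ANY* ELEVATED ANY* A1C
  - id: dm_history_elevated_glucose
    output: 35
    category: diabetes.unspecified
    seq: HISTORY ANY* ELEVATED GLUCOSE
  - id: dm_compl_history
    output: 36
    category: diabetes.unspecified
    seq: HISTORY ANY* DM_COMPL
  - id: dm2_insulin
    output: 15
    category: diabetes.type2
    seq: DM2 ANY* INSULIN
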