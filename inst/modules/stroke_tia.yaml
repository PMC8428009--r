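# Non-hemorrhagic stroke / TIA module: four categories. Hemorrhagic
# phrasings are declared in an absorber class (HEMORRHAGIC) that no
# pattern references: longest-match tagging then consumes "hemorrhagic
# stroke" whole, so the bare STROKE patterns cannot fire on it.
meta:
  name: stroke_tia
  version: "1.0"
concept: stroke_tia
wordclasses:
  ISCHEMIC_STROKE:
    - ischemic stroke
    - ischemic cva
    - ischemic cerebrovascular accident
    - ischemic infarct
    - cerebral infarction
    - cerebral infarct
    - lacunar stroke
    - lacunar infarct
    - watershed infarct
  EMBOLIC_STROKE:
    - embolic stroke
    - cardioembolic stroke
    - embolic cva
    - embolic infarct
    - cardioembolic event
  STROKE:
    - stroke
    - strokes
    - cva
    - cerebrovascular accident
  TIA:
    - tia
    - tias
    - transient ischemic attack
    - transient ischemic attacks
    - mini stroke
    - mini-stroke
  HEMORRHAGIC:
    - hemorrhagic stroke
    - hemorrhagic cva
    - intracranial hemorrhage
    - subarachnoid hemorrhage
    - intracerebral hemorrhage
  DEFICIT:
    - hemiparesis
    - aphasia
    - residual deficits
    - residual weakness
  LYTIC:
    - tpa
    - alteplase
    - thrombolysis
    - thrombectomy
  NEURO_SITE:
    - mca
    - middle cerebral artery
    - basilar
    - pons
    - cerebellar
    - basal ganglia
  HISTORY:
    - history of
    - hx of
    - h/o
    - known
    - prior
    - previous
    - remote
    - past medical history of
    - s/p
    - status post
  DIAGNOSIS:
    - diagnosis of
    - diagnosed with
    - carries a diagnosis of
patterns:
  # --- ischemic stroke ---
  - id: isch_mention
    output: 1
    category: stroke_tia.ischemic
    seq: ISCHEMIC_STROKE
  - id: isch_history
    output: 2
    category: stroke_tia.ischemic
    seq: HISTORY ANY* ISCHEMIC_STROKE
  - id: isch_diagnosis
    output: 3
    category: stroke_tia.ischemic
    seq: DIAGNOSIS ANY* ISCHEMIC_STROKE
  - id: isch_site
    output: 4
    category: stroke_tia.ischemic
    seq: ISCHEMIC_STROKE ANY* NEURO_SITE
  - id: isch_site_first
    output: 5
    category: stroke_tia.ischemic
    seq: NEURO_SITE ANY* ISCHEMIC_STROKE
  - id: isch_lytic
    output: 6
    category: stroke_tia.ischemic
    seq: ISCHEMIC_STROKE ANY* LYTIC
  # --- embolic stroke ---
  - id: emb_mention
    output: 10
    category: stroke_tia.embolic
    seq: EMBOLIC_STROKE
  - id: emb_history
    output: 11
    category: stroke_tia.embolic
    seq: HISTORY ANY* EMBOLIC_STROKE
  - id: emb_diagnosis
    output: 12
    category: stroke_tia.embolic
    seq: DIAGNOSIS ANY* EMBOLIC_STROKE
  - id: emb_site
    output: 13
    category: stroke_tia.embolic
    seq: EMBOLIC_STROKE ANY* NEURO_SITE
  - id: emb_lytic
    output: 14
    category: stroke_tia.embolic
    seq: EMBOLIC_STROKE ANY* LYTIC
  - id: isch_year
    output: 7
    category: stroke_tia.ischemic
    seq: ISCHEMIC_STROKE ANY* NUM
  - id: emb_year
    output: 15
    category: stroke_tia.embolic
    seq: EMBOLIC_STROKE ANY* NUM
  # --- unspecified stroke ---
  - id: stroke_mention
    output: 20
    category: stroke_tia.unspecified
    seq: STROKE
  - id: stroke_history
    output: 21
    category: stroke_tia.unspecified
    seq: HISTORY ANY* STROKE
  - id: stroke_diagnosis
    output: 22
    category: stroke_tia.unspecified
    seq: DIAGNOSIS ANY* STROKE
  - id: stroke_deficit
    output: 23
    category: stroke_tia.unspecified
    seq: STROKE ANY* DEFICIT
  - id: stroke_site
    output: 24
    category: stroke_tia.unspecified
    seq: STROKE ANY* NEURO_SITE
  - id: stroke_site_first
    output: 25
    category: stroke_tia.unspecified
    seq: NEURO_SITE ANY* STROKE
  - id: stroke_lytic
    output: 26
    category: stroke_tia.unspecified
    seq: STROKE ANY* LYTIC
  - id: stroke_year
    output: 27
    category: stroke_tia.unspecified
    seq: STROKE ANY* NUM
  # --- TIA ---
  - id: tia_mention
    output: 30
    category: stroke_tia.tia
    seq: TIA
  - id: tia_history
    output: 31
    category: stroke_tia.tia
    seq: HISTORY ANY* TIA
  - id: tia_diagnosis
    output: 32
    category: stroke_tia.tia
    seq: DIAGNOSIS ANY* TIA
  - id: tia_year
    output: 33
    category: stroke_tia.tia
    seq: TIA ANY* NUM
  - id: tia_deficit
    output: 34
    category: stroke_tia.tia
    seq: TIA ANY* DEFICIT
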