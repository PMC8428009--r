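# Coronary artery disease module: six categories. Numeric stenosis
# severity uses the NUM reserved class plus the num_ge_50_pct guard (the
# matched number must be >=50 with a percent sign) so "30% stenosis"
# does not fire the stenosis_gt50 category. A bare stenosis mention on a
# named coronary vessel resolves to the unspecified category.
meta:
  name: cad
  version: "1.0"
concept: cad
wordclasses:
  CAD:
    - cad
    - coronary artery disease
    - coronary disease
    - coronary heart disease
    - ischemic heart disease
    - ihd
    - coronary atherosclerosis
    - three-vessel disease
    - two-vessel disease
    - multivessel coronary disease
  MI:
    - mi
    - myocardial infarction
    - heart attack
    - nstemi
    - acs
    - acute coronary syndrome
    - non-st elevation myocardial infarction
  STEMI:
    - stemi
    - st elevation myocardial infarction
    - st-elevation myocardial infarction
    - st segment elevation myocardial infarction
    - st-segment elevation myocardial infarction
  UA:
    - unstable angina
  ANGINA:
    - angina
    - angina pectoris
    - anginal chest pain
  STENT:
    - stent
    - stents
    - stenting
    - angioplasty
    - ptca
    - drug-eluting stent
    - bare-metal stent
  CABG:
    - cabg
    - coronary artery bypass
    - coronary artery bypass graft
    - coronary artery bypass grafting
    - bypass surgery
    - bypass grafting
  PCI:
    - pci
    - percutaneous coronary intervention
    - coronary revascularization
    - revascularization
  CORONARY:
    - lad
    - rca
    - lcx
    - circumflex
    - left main
    - left anterior descending
    - right coronary artery
    - acute marginal
    - obtuse marginal
    - diagonal branch
    - coronary artery
    - coronary arteries
  STENOSIS:
    - stenosis
    - stenotic
    - occlusion
    - occluded
    - blockage
    - narrowing
  CATH:
    - cardiac catheterization
    - cath
    - coronary angiography
    - angiogram
  HISTORY:
    - history of
    - hx of
    - h/o
    - known
    - prior
    - previous
    - past medical history of
    - s/p
    - status post
  DIAGNOSIS:
    - diagnosis of
    - diagnosed with
    - carries a diagnosis of
patterns:
  # --- unspecified CAD ---
  - id: cad_mention
    output: 1
    category: cad.unspecified
    seq: CAD
  - id: cad_history
    output: 2
    category: cad.unspecified
    seq: HISTORY ANY* CAD
  - id: cad_diagnosis
    output: 3
    category: cad.unspecified
    seq: DIAGNOSIS ANY* CAD
  - id: cad_angina
    output: 4
    category: cad.unspecified
    seq: ANGINA
  # --- >50% coronary stenosis ---
  # (bare stenosis-on-vessel language deliberately does NOT fire
  # cad.unspecified: that category is for general CAD references that do
  # not meet one of the other defined categories)
  - id: cad_pct_stenosis
    output: 10
    category: cad.stenosis_gt50
    seq: NUM ANY* STENOSIS
    guard: num_ge_50_pct
  - id: cad_stenosis_pct
    output: 11
    category: cad.stenosis_gt50
    seq: STENOSIS ANY* NUM
    guard: num_ge_50_pct
  - id: cad_vessel_pct
    output: 12
    category: cad.stenosis_gt50
    seq: CORONARY ANY* NUM ANY* STENOSIS
    guard: num_ge_50_pct
  # --- unstable angina ---
  - id: ua_mention
    output: 20
    category: cad.unstable_angina
    seq: UA
  - id: ua_history
    output: 21
    category: cad.unstable_angina
    seq: HISTORY ANY* UA
  - id: ua_diagnosis
    output: 22
    category: cad.unstable_angina
    seq: DIAGNOSIS ANY* UA
  # --- myocardial infarction ---
  - id: mi_mention
    output: 30
    category: cad.mi
    seq: MI
  - id: mi_history
    output: 31
    category: cad.mi
    seq: HISTORY ANY* MI
  - id: mi_diagnosis
    output: 32
    category: cad.mi
    seq: DIAGNOSIS ANY* MI
  - id: mi_year
    output: 33
    category: cad.mi
    seq: MI ANY* NUM
  # --- STEMI ---
  - id: stemi_mention
    output: 40
    category: cad.stemi
    seq: STEMI
  - id: stemi_history
    output: 41
    category: cad.stemi
    seq: HISTORY ANY* STEMI
  - id: stemi_diagnosis
    output: 42
    category: cad.stemi
    seq: DIAGNOSIS ANY* STEMI
  # --- revascularization ---
  - id: revasc_stent_vessel
    output: 50
    category: cad.revascularization
    seq: NUM? STENT ANY* CORONARY
  - id: revasc_stent
    output: 51
    category: cad.revascularization
    seq: STENT
  - id: revasc_vessel_stent
    output: 52
    category: cad.revascularization
    seq: CORONARY ANY* STENT
  - id: revasc_cabg
    output: 53
    category: cad.revascularization
    seq: CABG
  - id: revasc_cabg_history
    output: 54
    category: cad.revascularization
    seq: HISTORY ANY* CABG
  - id: revasc_pci
    output: 55
    category: cad.revascularization
    seq: PCI
  - id: revasc_pci_history
    output: 56
    category: cad.revascularization
    seq: HISTORY ANY* PCI
  - id: revasc_stent_history
    output: 57
    category: cad.revascularization
    seq: HISTORY ANY* STENT
  - id: revasc_cath_stent
    output: 58
    category: cad.revascularization
    seq: CATH ANY* STENT
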