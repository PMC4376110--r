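# Default fall-risk knowledge base: community-dwelling adults aged 65+.
#
# Factor names and kinds follow the fall-risk ontology for this setting
# (24 dichotomous factors, 2 scalar factors, 1 synergy factor).
#
# NOTE ON VALUES: the odds_ratio and prevalence numbers below are EDITABLE
# PLACEHOLDERS in realistic ranges (see metadata.values_status). Transcribe
# values from a quantitative meta-analytic source before any clinical use.
schema_version: 1
prediction_span: 12 months
metadata:
  setting: community_dwelling
  values_status: placeholder
calibration:
  target_incidence: 0.31
factors:
- name: age
  kind: scalar
  max_level: 4
  odds_ratio: 1.12            # per 5-year band above 65
  level_prevalence: [0.30, 0.25, 0.20, 0.15, 0.10]
  level_map: {offset: -65.0, scale: 0.2}   # level = clamp(floor((age-65)/5), 0, 4)
  reversibility: irreversible
  setting: community_dwelling
- name: cognition impairment
  kind: dichotomous
  odds_ratio: 1.36
  prevalence: 0.12
  reversibility: irreversible
  setting: community_dwelling
- name: depression
  kind: dichotomous
  odds_ratio: 1.63
  prevalence: 0.15
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: diabetes
  kind: dichotomous
  odds_ratio: 1.19
  prevalence: 0.14
  reversibility: irreversible
  setting: community_dwelling
- name: comorbidity
  kind: synergy
  odds_ratio: 1.15            # per additional co-occurring chronic disease
  members: [diabetes, history of stroke, parkinson, rheumatic disease]
  reversibility: irreversible
  setting: community_dwelling
- name: dizziness and vertigo
  kind: dichotomous
  odds_ratio: 1.80
  prevalence: 0.20
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: fear of falling
  kind: dichotomous
  odds_ratio: 1.41
  prevalence: 0.30
  reversibility: surely_reversible
  setting: community_dwelling
- name: female sex
  kind: dichotomous
  odds_ratio: 1.30
  prevalence: 0.55
  reversibility: irreversible
  setting: community_dwelling
- name: gait problems
  kind: dichotomous
  odds_ratio: 2.06
  prevalence: 0.25
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: hearing impairment
  kind: dichotomous
  odds_ratio: 1.13
  prevalence: 0.30
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: history of falls
  kind: dichotomous
  odds_ratio: 2.77
  prevalence: 0.30
  reversibility: irreversible
  setting: community_dwelling
- name: history of stroke
  kind: dichotomous
  odds_ratio: 1.64
  prevalence: 0.07
  reversibility: irreversible
  setting: community_dwelling
- name: instrumental disability
  kind: dichotomous
  odds_ratio: 1.47
  prevalence: 0.20
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: living alone
  kind: dichotomous
  odds_ratio: 1.33
  prevalence: 0.30
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: number of medications
  kind: scalar
  max_level: 3
  odds_ratio: 1.06            # per medication beyond three
  level_prevalence: [0.45, 0.25, 0.18, 0.12]
  level_map: {offset: -3.0, scale: 1.0}    # level = clamp(n_meds - 3, 0, 3)
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: pain
  kind: dichotomous
  odds_ratio: 1.42
  prevalence: 0.35
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: parkinson
  kind: dichotomous
  odds_ratio: 2.71
  prevalence: 0.02
  reversibility: irreversible
  setting: community_dwelling
- name: physical activity limitation
  kind: dichotomous
  odds_ratio: 1.24
  prevalence: 0.35
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: physical disability
  kind: dichotomous
  odds_ratio: 1.56
  prevalence: 0.15
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: poor self-perceived health status
  kind: dichotomous
  odds_ratio: 1.27
  prevalence: 0.25
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: rheumatic disease
  kind: dichotomous
  odds_ratio: 1.45
  prevalence: 0.18
  reversibility: irreversible
  setting: community_dwelling
- name: urinary incontinence
  kind: dichotomous
  odds_ratio: 1.36
  prevalence: 0.20
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: use of antiepileptics
  kind: dichotomous
  odds_ratio: 1.88
  prevalence: 0.03
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: use of antihypertensives
  kind: dichotomous
  odds_ratio: 1.25
  prevalence: 0.45
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: use of sedatives
  kind: dichotomous
  odds_ratio: 1.38
  prevalence: 0.15
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: vision impairment
  kind: dichotomous
  odds_ratio: 1.35
  prevalence: 0.25
  reversibility: subject_specific_reversible
  setting: community_dwelling
- name: walking aid use
  kind: dichotomous
  odds_ratio: 2.18
  prevalence: 0.15
  reversibility: subject_specific_reversible
  setting: community_dwelling
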