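name: anticoagulant
description: Anticoagulant medications tracked in the cohort analysis.
match_policy: longest
terms:
  - warfarin
  - apixaban
  - dabigatran
  - rivaroxaban
  - edoxaban
  - betrixaban
groups:
  vitamin_k_antagonist:
    - warfarin
  direct_oral_anticoagulant:
    - apixaban
    - dabigatran
    - rivaroxaban
    - edoxaban
    - betrixaban
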