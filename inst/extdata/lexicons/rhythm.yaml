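name: rhythm
description: Rhythm-management medications tracked in the cohort analysis.
match_policy: longest
terms:
  - propafenone
  - disopyramide
  - quinidine
  - mexiletine
  - flecainide
  - metoprolol
  - carvedilol
  - labetalol
  - nadolol
  - propranolol
  - carteolol
  - penbutolol
  - pindolol
  - atenolol
  - betaxolol
  - bisoprolol
  - esmolol
  - nebivolol
  - timolol
  - sotalol
  - dofetilide
  - verapamil
  - diltiazem
  - nicardipine
  - amlodipine
  - felodipine
  - nifedipine
  - isradipine
  - nisoldipine
  - digoxin
groups:
  class_i:
    - propafenone
    - disopyramide
    - quinidine
    - mexiletine
    - flecainide
  class_ii:
    - metoprolol
    - carvedilol
    - labetalol
    - nadolol
    - propranolol
    - carteolol
    - penbutolol
    - pindolol
    - atenolol
    - betaxolol
    - bisoprolol
    - esmolol
    - nebivolol
    - timolol
  class_iii:
    - sotalol
    - dofetilide
  class_iv:
    - verapamil
    - diltiazem
    - nicardipine
    - amlodipine
    - felodipine
    - nifedipine
    - isradipine
    - nisoldipine
  other:
    - digoxin
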