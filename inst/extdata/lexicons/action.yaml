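name: action
description: >
  Action terms used to enrich sample relevance: verbs describing a device
  alerting a patient or a clinician recording the event.  Matching is by
  stem so inflected forms (notified, alerts, showing) count; irregular
  forms are listed explicitly.
match_policy: longest
terms:
  - alert
  - notify
  - warn
  - observe
  - identify
  - detect
  - note
  - record
  - capture
  - show
  - report
  - give
  - alarm
  - register
  - read
  - tell
  - have
  - had
  - see
  - saw
  - receive
  - get
  - got
  - notice
  - check
  - confirm
stems:
  - alert
  - notif
  - warn
  - observ
  - identif
  - detect
  - note
  - record
  - captur
  - show
  - report
  - giv
  - alarm
  - register
  - read
  - tell
  - hav
  - see
  - receiv
  - get
  - notic
  - check
  - confirm
irregular:
  - had
  - has
  - saw
  - seen
  - got
  - gotten
  - told
  - gave
  - shown
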