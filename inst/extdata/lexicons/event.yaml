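name: event
description: >
  Notification-event nouns: nominal forms of the action verbs, used by the
  labeling functions whose target patterns carry an event slot
  ("Got notification from wearable of AF").
match_policy: longest
terms:
  - notification
  - notifications
  - alert
  - alerts
  - alarm
  - alarms
  - reading
  - readings
  - recording
  - recordings
  - warning
  - warnings
  - notice
  - report
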