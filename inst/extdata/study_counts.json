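{
  "incident_sbp": {"events": 15, "n": 140},
  "prior_history_sbp": {"events": 5, "n": 25}
}
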