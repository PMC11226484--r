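{
  "title": "Pharmacist override entries (step S4)",
  "file": "overrides.csv",
  "columns": [
    {"name": "patient_id", "type": "string", "required": true},
    {"name": "medication", "type": "string", "required": true},
    {"name": "target_product", "type": "string", "required": true},
    {"name": "note", "type": "string", "required": false}
  ]
}
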