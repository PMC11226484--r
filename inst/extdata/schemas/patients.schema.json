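{
  "title": "Per-cohort patient demographics",
  "file": "patients.csv",
  "columns": [
    {"name": "patient_id", "type": "string", "required": true},
    {"name": "age", "type": "integer", "required": true},
    {"name": "department", "type": "string", "required": false}
  ]
}
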