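{
  "title": "Dosage-form equivalence classes",
  "file": "form_classes.csv",
  "columns": [
    {"name": "form", "type": "string", "required": true},
    {"name": "class", "type": "string", "required": true}
  ]
}
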