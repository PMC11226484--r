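{
  "title": "Hospital formulary",
  "file": "formulary.csv",
  "columns": [
    {"name": "product_name", "type": "string", "required": true},
    {"name": "dosage_form", "type": "string", "required": true},
    {"name": "atc", "type": "string", "required": false},
    {"name": "components", "type": "string", "required": true}
  ]
}
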