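{
  "title": "Drug-drug interaction table",
  "file": "interactions.csv",
  "columns": [
    {"name": "ingredient_a", "type": "string", "required": true},
    {"name": "ingredient_b", "type": "string", "required": true},
    {"name": "severity", "type": "string", "required": false}
  ]
}
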