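{
  "title": "Substitution-exclusion list",
  "file": "exclusion_list.csv",
  "columns": [
    {"name": "ingredient", "type": "string", "required": true},
    {"name": "salt", "type": "string", "required": false}
  ]
}
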