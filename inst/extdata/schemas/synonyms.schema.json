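{
  "title": "Ingredient synonym map",
  "file": "synonyms.csv",
  "columns": [
    {"name": "alias", "type": "string", "required": true},
    {"name": "canonical", "type": "string", "required": true}
  ]
}
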