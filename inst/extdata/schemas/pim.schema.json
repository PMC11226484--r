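{
  "title": "Potentially-inappropriate-medication catalogs",
  "file": "pim.csv",
  "columns": [
    {"name": "ingredient", "type": "string", "required": true},
    {"name": "catalog", "type": "string", "required": true, "enum": ["priscus", "forta"]},
    {"name": "category", "type": "string", "required": false, "enum": ["A", "B", "C", "D"]}
  ]
}
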