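{
  "title": "Dose-equivalence tables",
  "file": "equivalence.csv",
  "columns": [
    {"name": "table_id", "type": "string", "required": true},
    {"name": "source_ingredient", "type": "string", "required": true},
    {"name": "source_strength", "type": "string", "required": true},
    {"name": "target_ingredient", "type": "string", "required": true},
    {"name": "target_strength", "type": "string", "required": true},
    {"name": "match_level", "type": "integer", "required": true, "enum": ["4", "5"]}
  ]
}
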