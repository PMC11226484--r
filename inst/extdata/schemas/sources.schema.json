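{
  "title": "Per-cohort medication source records",
  "file": "sources.csv",
  "columns": [
    {"name": "patient_id", "type": "string", "required": true},
    {"name": "source", "type": "string", "required": true, "enum": ["interview", "medication_list", "medical_documents"]},
    {"name": "product_name", "type": "string", "required": false},
    {"name": "ingredients", "type": "string", "required": false},
    {"name": "dosage_form", "type": "string", "required": false},
    {"name": "atc", "type": "string", "required": false},
    {"name": "administration_times", "type": "string", "required": false},
    {"name": "prescribed_during_stay", "type": "boolean", "required": false},
    {"name": "self_medication", "type": "boolean", "required": false}
  ]
}
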