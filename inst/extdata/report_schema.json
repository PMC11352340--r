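{
  "title": "oligosig pipeline report",
  "required_summary_fields": {
    "n_candidates": "integer",
    "n_shared": "integer",
    "class_counts": "object",
    "n_functional": "integer",
    "rna_panel_size": "integer",
    "n_loh": "integer"
  },
  "required_variant_columns": [
    "case_id", "key", "gene", "consequence", "class", "functional",
    "rna_panel", "loh"
  ]
}
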