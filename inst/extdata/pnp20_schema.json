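{
  "id": "structure_id",
  "endpoint": "zeta_mV",
  "split": "split",
  "core_name": "core",
  "coating_name": "coating",
  "reference_pred": "zeta_ref_pred_mV",
  "columns": [
    {"name": "AMW-P", "block": "core", "kind": "continuous"},
    {"name": "nCsp2-C", "block": "coating", "kind": "count"},
    {"name": "CC1rs", "block": "corona", "kind": "binary"},
    {"name": "ApoA-I", "block": "corona", "kind": "binary"},
    {"name": "kininogen-1", "block": "corona", "kind": "binary"}
  ]
}
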