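{
  "version": "synthetic-1",
  "comment": "SYNTHETIC stand-in thresholds for testing and simulation; not the regulator-published values. Limits are strict upper bounds per serving, gated on the product's added-ingredient flags.",
  "basis": "per_serving",
  "rule": "any_exceed",
  "thresholds": {
    "saturated_fat_g": { "limit": 2.0,   "added_flag": "added_fat" },
    "sugars_g":        { "limit": 5.0,   "added_flag": "added_sugar" },
    "sodium_mg":       { "limit": 200.0, "added_flag": "added_sodium" }
  }
}
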