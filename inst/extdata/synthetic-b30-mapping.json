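{
  "id_column": "patient_id",
  "time_column": "timepoint",
  "response_column": "Numbness and tingling",
  "time_order": ["Baseline", "Cycle 4 Day 1", "6-month follow-up", "12-month follow-up", "18-month follow-up", "24-month follow-up"],
  "response_order": ["Not at all", "Slightly", "Moderately", "Quite a bit", "Extremely"],
  "arm_column": "arm",
  "missing_label": "No Response"
}
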