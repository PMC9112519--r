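{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "risk_functions",
  "description": "Per-disease, per-age-band relative risks of disease incidence per 10 mmHg systolic blood pressure (GBD-style log-linear risk functions). Optional rr_lo/rr_hi give a 95% CI used by the Monte Carlo uncertainty module. The per-mmHg log-RR slope is beta = ln(rr_per_10mmhg)/10.",
  "type": "object",
  "required": ["disease", "age_group", "rr_per_10mmhg"],
  "properties": {
    "disease": {"enum": ["ihd", "isch_stroke", "haem_stroke"]},
    "age_group": {"type": "string", "pattern": "^[0-9]+-[0-9]+$"},
    "rr_per_10mmhg": {"type": "number", "exclusiveMinimum": 0},
    "rr_lo": {"type": "number", "exclusiveMinimum": 0},
    "rr_hi": {"type": "number", "exclusiveMinimum": 0},
    "source": {"type": "string"}
  }
}
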