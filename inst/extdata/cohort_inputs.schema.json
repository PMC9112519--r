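{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "cohort_inputs",
  "description": "Age/sex-stratified base-year epidemiological inputs. One row per sex x 5-year age band. Incidence (IR), disability (DR) and all-cause mortality rates are stated per 100,000 persons in the file and converted to per-person rates on load; case-fatality rates (CFR) are per prevalent case-year. Systolic blood pressure columns are empty below age 15.",
  "type": "object",
  "required": ["sex", "age_group", "n", "prevalence_pct", "mortality_per_100k",
               "morbidity_prop", "ihd_ir_per_100k", "ihd_cfr", "ihd_dr_per_100k",
               "isch_stroke_ir_per_100k", "isch_stroke_cfr", "isch_stroke_dr_per_100k",
               "haem_stroke_ir_per_100k", "haem_stroke_cfr", "haem_stroke_dr_per_100k"],
  "properties": {
    "sex": {"enum": ["male", "female"]},
    "age_group": {"type": "string", "pattern": "^[0-9]+-[0-9]+$"},
    "n": {"type": "integer", "minimum": 0},
    "prevalence_pct": {"type": "number", "minimum": 0, "maximum": 100},
    "mortality_per_100k": {"type": "number", "minimum": 0},
    "morbidity_prop": {"type": "number", "minimum": 0, "maximum": 1},
    "sbp_mean": {"type": ["number", "null"], "exclusiveMinimum": 0},
    "sbp_sd": {"type": ["number", "null"], "exclusiveMinimum": 0},
    "ihd_ir_per_100k": {"type": "number", "minimum": 0},
    "ihd_cfr": {"type": "number", "minimum": 0},
    "ihd_dr_per_100k": {"type": "number", "minimum": 0},
    "isch_stroke_ir_per_100k": {"type": "number", "minimum": 0},
    "isch_stroke_cfr": {"type": "number", "minimum": 0},
    "isch_stroke_dr_per_100k": {"type": "number", "minimum": 0},
    "haem_stroke_ir_per_100k": {"type": "number", "minimum": 0},
    "haem_stroke_cfr": {"type": "number", "minimum": 0},
    "haem_stroke_dr_per_100k": {"type": "number", "minimum": 0}
  }
}
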