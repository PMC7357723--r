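{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Pre-season farmer field interview",
  "type": "object",
  "required": ["field_id", "field_area", "season", "irrigation_source",
               "variety", "establishment", "sowing_date",
               "establishment_date", "historical_yield", "prev_residue"],
  "properties": {
    "field_id": {"type": "string"},
    "field_area": {"type": "number", "exclusiveMinimum": 0,
                   "description": "hectares"},
    "season": {"enum": ["kuruvai", "samba", "thaladi"]},
    "irrigation_source": {"enum": ["tube_well", "canal", "rain_plus_canal"]},
    "variety": {
      "type": "object",
      "required": ["name", "duration", "baseline_yield_lo",
                   "baseline_yield_hi"],
      "properties": {
        "name": {"type": "string"},
        "duration": {"type": "number", "minimum": 100, "maximum": 160,
                     "description": "total growth duration, days"},
        "baseline_yield_lo": {"type": "number", "minimum": 0},
        "baseline_yield_hi": {"type": "number", "minimum": 0}
      }
    },
    "establishment": {"enum": ["transplanted", "wet_seeded", "dry_seeded"]},
    "seedling_age": {"type": "number", "minimum": 1,
                     "description": "days; required iff transplanted"},
    "sowing_date": {"type": "string", "format": "date"},
    "establishment_date": {"type": "string", "format": "date"},
    "historical_yield": {"type": "number", "minimum": 3.0, "maximum": 8.0,
                         "description": "Mg/ha grain at 14% moisture"},
    "prev_residue": {"enum": ["removed", "retained_combine"]},
    "selected_products": {"type": "array", "items": {"type": "string"}}
  }
}
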