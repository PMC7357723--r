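{
  "field_id": "demo-001",
  "field_area": 0.5,
  "season": "kuruvai",
  "irrigation_source": "tube_well",
  "variety": {
    "name": "ADT 43",
    "duration": 110,
    "baseline_yield_lo": 5.0,
    "baseline_yield_hi": 6.5
  },
  "establishment": "transplanted",
  "seedling_age": 25,
  "sowing_date": "2014-06-10",
  "establishment_date": "2014-07-05",
  "historical_yield": 4.8,
  "prev_residue": "removed",
  "selected_products": ["DAP", "MOP"]
}
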