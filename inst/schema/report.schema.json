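{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "ecvlge quantification report",
  "type": "object",
  "required": ["version", "method", "scar_percent", "scar_mass_g", "lv_mass_g", "selection"],
  "properties": {
    "version": {"type": "string"},
    "seed": {"type": "number"},
    "config": {"type": "object"},
    "method": {"type": "string"},
    "scar_percent": {"type": "number"},
    "scar_mass_g": {"type": "number"},
    "lv_mass_g": {"type": "number"},
    "per_segment_percent": {"type": "object"},
    "selection": {
      "type": "object",
      "required": ["method", "absolute_threshold", "scenario"],
      "properties": {
        "method": {"type": "string"},
        "n": {"type": "number"},
        "absolute_threshold": {"type": "number"},
        "scenario": {"type": "string"}
      }
    },
    "roi_ecv": {"type": "number"},
    "scenario": {"type": "string"},
    "mid_slice_dice": {"type": "number"}
  }
}
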