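{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "rabiestrace schematic atlas table",
  "description": "One row per brain-region footprint. Coordinates are section coordinates in micrometers with the origin on the midline (x > 0 = right hemisphere); AP bounds are millimeters relative to bregma (negative = posterior). Footprints are given for the left hemisphere; rows with side_rule 'mirror' are reflected across the midline for the right hemisphere, rows with side_rule 'midline' are used as-is and assigned side 'midline'.",
  "type": "object",
  "required": ["region", "side_rule", "ap_min", "ap_max", "polygon"],
  "properties": {
    "region": {
      "type": "string",
      "enum": ["CA1_Py", "CA1_Or", "CA1_Rad", "CA1_LMol", "CA2_Py", "CA2_Or",
               "CA3_Py", "CA3_Or", "MS_DB", "SUB", "EC", "MnR_PMnR", "ReN", "OTHER"]
    },
    "side_rule": {"type": "string", "enum": ["mirror", "midline"]},
    "ap_min": {"type": "number", "description": "posterior AP bound, mm from bregma"},
    "ap_max": {"type": "number", "description": "anterior AP bound, mm from bregma; ap_min < ap_max"},
    "polygon": {
      "type": "string",
      "description": "semicolon-separated 'x y' vertices (micrometers), closed implicitly"
    }
  }
}
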