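{
  "title": "allomap run report",
  "type": "object",
  "required": ["seed", "package_version", "stage_seeds", "stages", "outputs"],
  "properties": {
    "seed": {"type": "integer"},
    "package_version": {"type": "string"},
    "stage_seeds": {"type": "object"},
    "stages": {
      "type": "object",
      "additionalProperties": {
        "type": "object",
        "additionalProperties": {"type": "number", "minimum": 0}
      }
    },
    "outputs": {"type": "object"}
  }
}
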