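{
  "name": "reference",
  "description": "Sensors near the heart, light chest-band pressure, quiet room.",
  "sim": {},
  "radar": {},
  "channels": {}
}
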