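{
  "name": "background-sound",
  "description": "Loud music at ~0.5 m: acoustic interference enters the stethoscope only; radar and accelerometer do not pick up airborne sound.",
  "channels": {"background_level": 2.0}
}
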