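{
  "name": "opposite-side",
  "description": "Contact sensors on the right side of the chest, far from the heart; the radar beam is steered to the displaced target angle.",
  "radar": {"theta": 20},
  "channels": {"accel_damping": 0.3, "stetho_damping": 0.35}
}
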