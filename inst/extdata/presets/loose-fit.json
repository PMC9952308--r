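{
  "name": "loose-fit",
  "description": "Chest band worn loosely: the stethoscope resonator loses acoustic coupling; the accelerometer stays adequately coupled.",
  "channels": {"stetho_damping": 0.25, "accel_damping": 1.0}
}
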