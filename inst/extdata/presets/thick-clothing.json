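{
  "name": "thick-clothing",
  "description": "Two additional sweatshirts: the accelerometer loses coupling through fabric, the stethoscope is barely affected, the radar return is mildly attenuated.",
  "radar": {"reflectivity": 0.8},
  "channels": {"accel_damping": 0.35, "stetho_damping": 0.9}
}
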