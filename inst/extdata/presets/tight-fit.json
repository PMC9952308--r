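{
  "name": "tight-fit",
  "description": "Chest band as tight as comfortable: band pressure damps skin vibration under both contact sensors.",
  "channels": {"stetho_damping": 0.4, "accel_damping": 0.4}
}
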