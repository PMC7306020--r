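{
  "comment": "Default occiput-posterior descent trajectory. Anchored values: 100.0 mm total anterior displacement, internal rotation 45 deg at engagement completed (0 deg) at station +3, 20 deg flexion at the midpelvis (station 0) waypoint increasing toward the outlet. Intermediate displacement/caudal values are neutral placeholders, not measured data. Units: station cm (ischial-spine plane = 0, negative above), displacements mm (anterior = +x, caudal = +z), rotations deg.",
  "presentation": "OP",
  "rotation_complete_station": 3,
  "waypoints": {
    "station_cm": [-3, 0, 3, 5, 8],
    "anterior_mm": [0, 35, 60, 80, 100],
    "caudal_mm": [0, 40, 75, 100, 130],
    "internal_rotation_deg": [45, 20, 0, 0, 0],
    "flexion_deg": [0, 20, 20, 30, 45]
  }
}
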