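{
  "comment": "Default occiput-anterior descent trajectory (uncomplicated cardinal movements): internal rotation completed at the ischial-spine plane (station 0); the head follows the curved canal axis with earlier flexion than the OP case. All values other than the 100.0 mm total anterior displacement are neutral placeholders, not measured data. Units: station cm, displacements mm (anterior = +x, caudal = +z), rotations deg.",
  "presentation": "OA",
  "rotation_complete_station": 0,
  "waypoints": {
    "station_cm": [-3, 0, 3, 5, 8],
    "anterior_mm": [0, 35, 60, 80, 100],
    "caudal_mm": [0, 45, 80, 100, 120],
    "internal_rotation_deg": [45, 0, 0, 0, 0],
    "flexion_deg": [10, 20, 30, 35, 40]
  }
}
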