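{
  "id": "example",
  "sex": "F",
  "heart_rate_bpm": 64,
  "aha_segment": "LAD_prox",
  "stenosis_pct": 50,
  "material": "mixed",
  "lumen_enhancement_hu": 450,
  "rotation_time_s": 0.28,
  "n_sources": 2,
  "n_segments": 1,
  "pixel_size_mm": 0.45,
  "slice_thickness_mm": 0.625,
  "slice_interval_mm": 0.5,
  "nps_peak_mm1": 0.25,
  "noise_sigma_hu": 30,
  "velocity_mm_s": 20,
  "diameter_mm": 3.0,
  "quality_label": "unknown"
}
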