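schema_version: 1
balloon:
  diameter_mm: 23
  cyl_length_mm: 40
  total_length_mm: 75
  thickness_mm: 0.09
  shaft_radius_mm: 3
material:
  type: ogden
  mu: [-4715.57, 2480.94, 2479.35]
  alpha: [4.89, 6.90, 1.13]
  delta: [1.38, 0, 0]
  units: MPa
  poisson: 0.45
phantom:
  diameter_mm: 22
  thickness_mm: 1.2
  length_mm: 75
  end_band_mm: 5
phantom_material:
  type: linear
  young_modulus_MPa: 13.19
  poisson: 0.25
protocol:
  flow_rate_ml_h: 40
  injected_ml: 1.5
  dT_s: 15
noise:
  seed: 1
  pressure_sd_mmHg: 5
  diameter_quant_mm: 0.5
solver:
  n_elements: 100
  dV_max_ml: 0.25
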