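# Example chaoswidow configuration. Omitted keys fall back to the package
# defaults (see default_config()).
chaos:
  mu: 2.0
  # x0: 0.37          # fixed chaotic seed; omit to draw from the run seed
  collapse_epsilon: 1.0e-12
bwoa:
  population_size: 20
  max_iterations: 50
  m_range: [0.4, 0.9]
  beta_range: [-1.0, 1.0]
  pheromone_threshold: 0.3
  lambda_weight: 0.5
  perturbation_scale: 0.1
  use_tent: true
  use_sharpen: true
  movement_sign: attractive   # or "as_printed"
bounds:
  # gaussian_sigma, gaussian_ksize, median_ksize, mean_ksize,
  # bilateral_sigma_r, bilateral_sigma_d, bilateral_ksize, sharpen_amount
  lower: [0.3, 0.0, 0.0, 0.0,  5.0, 0.5, 0.0, 0.0]
  upper: [3.0, 1.0, 1.0, 1.0, 75.0, 5.0, 1.0, 2.0]
rois:
  # 0-based half-open rectangles [row0, col0, row1, col1]; null = defaults
  enl: null
  epi: null
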