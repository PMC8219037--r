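# Example scleromorph pipeline configuration.
# Any omitted key falls back to default_pipeline_config().
seed: 42
outdir: scleromorph-out
synth:
  n_per_stage: 2
  base_radius: 5
  n_stages: 3
  spacing: [0.6, 0.6, 0.6]
  tissue:
    n_cells: 8
    domain_size: [30, 30, 30]
    wall_thickness: 0
    ics_fraction: 0.3
    spacing: [0.75, 0.75, 0.75]
  cube:
    shape: [24, 24]
    endmembers: [cellulose, pectin_de_high]
    noise_sd: 0.02
    n_spikes: 3
measure:
  smoothing_radius: 2
raman:
  k: 2
  max_iter: 300
  tol: 1.0e-7
  band_window: [2831, 3009]
  despike_z: 8
  omp_max_atoms: 3
stats:
  alpha: 0.05
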