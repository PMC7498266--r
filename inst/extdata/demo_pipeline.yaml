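# Minimal synthetic end-to-end pipeline configuration.
# Run with:  Rscript inst/scripts/mapkdyn.R run --config demo_pipeline.yaml --out out/
seed: 11
frame_interval_min: 5
stages: [simulate, peaks, migration, extrusion, edu, shed]
simulate:
  tracks:
    n_cells: 40
    n_frames: 73
    bias_kappa: 2
    inducible_fraction: 0.15
    bias_onset_min: 120
  zstack:
    n_positions: 2
    n_baseline: 2
    nx: 80
    ny: 80
    n_nuclei: 30
    extrusion_offset_um: 6
  edu:
    n_positions: 8
  shed:
    n_proteins: 60
    n_hits: 5
    effect_lnfc: 1.2
peaks:
  min_amplitude: 0.15
  min_slope: 0.005
  fall_fraction: 0.5
  min_coverage: 0.667
migration:
  interval_min: 20
  half_width_um: 100
  epoch_before: [0, 120]
  epoch_after: [120, 360]
  n_iter: 200
  n_sub: 500
extrusion: {}
edu: {}
shed:
  p_max: 0.05
  fc_min: 1.5
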