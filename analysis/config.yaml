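# Shared settings for the analysis scripts (01..06).
# The virtual species emulates a coastal NW-Pacific benthic species whose
# southern range limit is set by a dispersal barrier at the Yangtze-estuary
# latitude, not by climate.
virtual_species:
  extent: [118, 130, 28, 40]   # lon_min, lon_max, lat_min, lat_max (deg)
  resolution: 0.1              # deg; 120 x 120 grid
  n_env: 4
  barrier_lat: 31.5            # deg N
  n_presence: 300
  expert_buffer_km: 50         # commission error of the expert polygon
  seed: 1
prep:
  thin_resolution: 0.1         # one record per environmental grid cell
  corr_threshold: 0.7
  buffer_km: 1000
  n_background: 10000
evaluation:
  k_folds: 10
  omission_rate: 0.10
stacking:
  mode: out_of_fold
experiment:
  seeds: [1, 2, 3, 4, 5, 6, 7, 8, 9, 10]
paths:
  fixtures: results/fixtures
  results: results
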