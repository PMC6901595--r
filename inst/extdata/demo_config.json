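{
  "seed": 7,
  "acquisition": {
    "rep_rate": 8e7,
    "n_time_bins": 256,
    "image_shape": [64, 64],
    "lambda_min": 410,
    "lambda_max": 696,
    "n_channels": 32,
    "channel_width": 8.9,
    "harmonic": 1,
    "irf_fwhm": 0
  },
  "scene": {
    "n_cells": 6,
    "granule_photons": 300,
    "cytoplasm_photons": 30,
    "n_granules": 25,
    "n_processes": 3
  },
  "analysis": {
    "harmonic": 1,
    "threshold": 20,
    "calibration_tau": 4.1,
    "efilter_passes": 1,
    "efilter_kernel": 3,
    "n_cursors": 7,
    "cursor_radius": 0.04,
    "alpha": 0.05,
    "modality": "flim"
  }
}
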