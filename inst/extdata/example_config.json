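{
  "optics": {
    "camera_pixel_size": 110,
    "psf_sigma": 143,
    "spectral_dispersion": 2,
    "split_ratio": 0.75,
    "background_rate": 1,
    "read_noise_sd": 1.5,
    "fov": [7.04, 7.04],
    "mode": "labeled"
  },
  "density": 0.1,
  "dyes": ["AF647"],
  "filter_window": [640, 700],
  "drift": {"n_bins": 10, "render_pixel": 10},
  "regression": {"radius_nm": 50, "spectral_tol_nm": 10, "max_gap": 5},
  "render": {"pixel_nm": 10, "blur_sigma_nm": 10},
  "seed": 1
}
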