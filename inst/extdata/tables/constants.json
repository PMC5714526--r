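{
  "Lambda_cGy_per_h_per_U": 1.14,
  "Lambda_uncertainty": 0.04,
  "Sk_U_per_mCi": 1.082,
  "air_kerma_rate_cGy_per_h_per_mCi": 1.981e-4,
  "poly_coefficients": [0.919, 0.0952, -0.0139, 0.00277, -0.000412, 1.96e-05],
  "poly_r_squared": 0.999,
  "active_length_cm": 0.6
}
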