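# Ytterbium-169 photon emission spectrum: gamma lines and Tm K x-rays.
# Compiled from published nuclear decay data evaluations (ENSDF/NuDat-style
# line lists, rounded); 169Yb decays by electron capture to 169Tm
# (T1/2 ~ 32.0 d). Intensities are absolute, photons per decay.
# Intensity-weighted mean energy of this list: 93.6 keV; total yield 3.258.
# columns: energy_keV photons_per_decay
49.77   0.525
50.74   0.928
57.50   0.266
59.20   0.0705
63.12   0.4362
93.61   0.0258
109.78  0.1739
118.19  0.0187
130.52  0.1138
177.21  0.2228
197.96  0.3593
261.08  0.0171
307.74  0.1005
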