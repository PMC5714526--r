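# Photon mass interaction coefficients for Ni (Z=28, A=58.693)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 2.06826271e+02 1.84001615e-01 1.40586420e+00 2.06829723e+02
10.816491 1.68200024e+02 1.83450811e-01 1.28095875e+00 1.68203735e+02
11.699647 1.36444060e+02 1.82859907e-01 1.16569187e+00 1.36448046e+02
12.654913 1.10510169e+02 1.82226385e-01 1.05983373e+00 1.10514449e+02
13.688174 8.93657257e+01 1.81547633e-01 9.62864361e-01 8.93703190e+01
14.805801 7.21533321e+01 1.80820950e-01 8.74052957e-01 7.21582584e+01
16.014681 5.81640016e+01 1.80043560e-01 7.92562273e-01 5.81692815e+01
17.322265 4.67901015e+01 1.79212615e-01 7.17558266e-01 4.67957567e+01
18.736612 3.75724196e+01 1.78325220e-01 6.48300395e-01 3.75784722e+01
19.989500 3.13238099e+01 1.77548837e-01 5.95081488e-01 3.13302075e+01
20.009500 3.12356962e+01 1.77536517e-01 5.94285318e-01 3.12420992e+01
20.266439 3.01324419e+01 1.77378440e-01 5.84194809e-01 3.01389148e+01
21.921175 2.41347480e+01 1.76369327e-01 5.24807023e-01 2.41416648e+01
23.711019 1.93059407e+01 1.75294940e-01 4.69844525e-01 1.93133253e+01
25.647001 1.54236855e+01 1.74152374e-01 4.18988079e-01 1.54315621e+01
27.741055 1.23027642e+01 1.72938791e-01 3.71573698e-01 1.23111574e+01
30.006087 9.79998427e+00 1.71651450e-01 3.28233585e-01 9.80891844e+00
32.456056 7.79870206e+00 1.70287750e-01 2.89189314e-01 7.80820159e+00
35.106063 6.19997115e+00 1.68845267e-01 2.54293394e-01 6.21006003e+00
37.972440 4.91780425e+00 1.67321801e-01 2.23243961e-01 4.92850584e+00
41.072855 3.89543204e+00 1.65715418e-01 1.95691476e-01 3.90676887e+00
44.426415 3.08377098e+00 1.64024502e-01 1.71288191e-01 3.09576445e+00
48.053791 2.43976557e+00 1.62247803e-01 1.49708502e-01 2.45243567e+00
51.977339 1.92908415e+00 1.60384482e-01 1.30655266e-01 1.94244921e+00
56.221240 1.52436561e+00 1.58434165e-01 1.13859912e-01 1.53844193e+00
60.811652 1.20381563e+00 1.56396980e-01 9.90802464e-02 1.21861725e+00
61.322300 1.17387132e+00 1.56174836e-01 9.76151614e-02 1.18875093e+00
61.342300 1.17271864e+00 1.56166153e-01 9.75584375e-02 1.18760130e+00
65.776867 9.50083625e-01 1.54273602e-01 8.60977227e-02 9.65621997e-01
71.147488 7.49364353e-01 1.52065287e-01 7.47148909e-02 7.65648082e-01
76.956614 5.90679704e-01 1.49773893e-01 6.47532508e-02 6.07714294e-01
83.240051 4.65304791e-01 1.47401903e-01 5.60514817e-02 4.83092418e-01
90.036524 3.66309550e-01 1.44952426e-01 4.84639892e-02 3.84848882e-01
97.387922 2.88192801e-01 1.42429195e-01 4.18596331e-02 3.07478851e-01
105.339556 2.26590264e-01 1.39836541e-01 3.61206338e-02 2.46614306e-01
113.940433 1.78041725e-01 1.37179365e-01 3.11415359e-02 1.98791250e-01
123.243564 1.39805448e-01 1.34463089e-01 2.68282188e-02 1.61264187e-01
133.306287 1.09710349e-01 1.31693591e-01 2.30969724e-02 1.31858348e-01
144.190622 8.60383093e-02 1.28877136e-01 1.98735978e-02 1.08852060e-01
155.963653 6.74305312e-02 1.26020290e-01 1.70925202e-02 9.08831568e-02
168.697940 5.28130838e-02 1.23129828e-01 1.46959613e-02 7.68745634e-02
182.471971 4.13377274e-02 1.20212635e-01 1.26331595e-02 6.59751627e-02
197.370639 3.23349195e-02 1.17275609e-01 1.08596032e-02 5.75128264e-02
213.485768 2.52765139e-02 1.14325559e-01 9.33638988e-03 5.09571328e-02
230.916684 1.97461737e-02 1.11369111e-01 8.02952052e-03 4.58897863e-02
249.770817 1.54159176e-02 1.08412625e-01 6.90944210e-03 4.19811604e-02
270.164373 1.20275400e-02 1.05462116e-01 5.95043799e-03 3.89717067e-02
292.223044 9.37790153e-03 1.02523196e-01 5.13030750e-03 3.66572260e-02
316.082785 7.30729189e-03 9.96010256e-02 4.42981708e-03 3.48772077e-02
341.890651 5.69022898e-03 9.67002826e-02 3.83236547e-03 3.35056016e-02
369.805707 4.42818919e-03 9.38251505e-02 3.32381079e-03 3.24435211e-02
400.000000 3.44386741e-03 9.09793182e-02 2.89173007e-03 3.16134780e-02
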