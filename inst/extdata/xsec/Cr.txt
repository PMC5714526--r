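# Photon mass interaction coefficients for Cr (Z=24, A=51.996)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 1.37200472e+02 1.78029192e-01 1.05445839e+00 1.37203812e+02
10.816491 1.10784977e+02 1.77496266e-01 9.66317760e-01 1.10788567e+02
11.699647 8.93148380e+01 1.76924541e-01 8.84824911e-01 8.93186950e+01
12.654913 7.18324087e+01 1.76311582e-01 8.09282377e-01 7.18365501e+01
13.688174 5.76725532e+01 1.75654861e-01 7.38976297e-01 5.76769974e+01
14.805801 4.62456769e+01 1.74951766e-01 6.73272064e-01 4.62504432e+01
16.014681 3.70375749e+01 1.74199608e-01 6.11675095e-01 3.70426835e+01
17.322265 2.96265036e+01 1.73395635e-01 5.53850834e-01 2.96319752e+01
18.736612 2.36691108e+01 1.72537044e-01 4.99612514e-01 2.36749669e+01
19.989500 1.96503376e+01 1.71785861e-01 4.57528448e-01 1.96565275e+01
20.009500 1.95937973e+01 1.71773941e-01 4.56896988e-01 1.95999925e+01
20.266439 1.88861959e+01 1.71620995e-01 4.48890468e-01 1.88924587e+01
21.921175 1.50510147e+01 1.70644636e-01 4.01693555e-01 1.50577070e+01
23.711019 1.19796374e+01 1.69605122e-01 3.58068021e-01 1.19867823e+01
25.647001 9.52305079e+00 1.68499642e-01 3.18020792e-01 9.53067175e+00
27.741055 7.55196784e+00 1.67325450e-01 2.81407973e-01 7.56008855e+00
30.006087 5.97705743e+00 1.66079894e-01 2.48324451e-01 5.98570161e+00
32.456056 4.72779449e+00 1.64760458e-01 2.18666961e-01 4.73698568e+00
35.106063 3.73741731e+00 1.63364796e-01 1.92203577e-01 3.74717871e+00
37.972440 2.95273560e+00 1.61890779e-01 1.68659984e-01 2.96308983e+00
41.072855 2.33139442e+00 1.60336537e-01 1.47759761e-01 2.34236327e+00
44.426415 1.83968540e+00 1.58700506e-01 1.29241293e-01 1.85128958e+00
48.053791 1.45079651e+00 1.56981476e-01 1.12863389e-01 1.46305537e+00
51.977339 1.14341321e+00 1.55178636e-01 9.84059364e-02 1.15634446e+00
56.221240 9.00600980e-01 1.53291623e-01 8.56686473e-02 9.14220405e-01
60.811652 7.08913060e-01 1.51320562e-01 7.44693186e-02 7.23234240e-01
61.322300 6.91039992e-01 1.51105629e-01 7.33597727e-02 7.05436638e-01
61.342300 6.90352114e-01 1.51097228e-01 7.33168166e-02 7.04751705e-01
65.776867 5.57678422e-01 1.49266106e-01 6.46421626e-02 5.72712441e-01
71.147488 4.38433822e-01 1.47129469e-01 5.60364010e-02 4.54189006e-01
76.956614 3.44471058e-01 1.44912451e-01 4.85150831e-02 3.60952730e-01
83.240051 2.70476245e-01 1.42617452e-01 4.19540953e-02 2.87686512e-01
90.036524 2.12242582e-01 1.40247482e-01 3.62412865e-02 2.30180154e-01
97.387922 1.66441759e-01 1.37806151e-01 3.12756522e-02 1.85101812e-01
105.339556 1.30442139e-01 1.35297651e-01 2.69665641e-02 1.49816229e-01
113.940433 1.02164234e-01 1.32726723e-01 2.32330053e-02 1.22240260e-01
123.243564 7.99658963e-02 1.30098613e-01 2.00028164e-02 1.00728116e-01
133.306287 6.25511554e-02 1.27419009e-01 1.72119606e-02 8.39802621e-02
144.190622 4.88978962e-02 1.24693972e-01 1.48037982e-02 7.09711460e-02
155.963653 3.82005036e-02 1.21929855e-01 1.27283884e-02 6.08918912e-02
168.697940 2.98244123e-02 1.19133213e-01 1.09418241e-02 5.31048915e-02
182.471971 2.32701111e-02 1.16310709e-01 9.40560758e-03 4.71078512e-02
197.370639 1.81446536e-02 1.13469014e-01 8.08606764e-03 4.25053224e-02
213.485768 1.41391245e-02 1.10614718e-01 6.95384103e-03 3.89861880e-02
230.916684 1.10108273e-02 1.07754232e-01 5.98336993e-03 3.63058564e-02
249.770817 8.56921426e-03 1.04893709e-01 5.15249418e-03 3.42721880e-02
270.164373 6.66477845e-03 1.02038970e-01 4.44201369e-03 3.27343768e-02
292.223044 5.18029123e-03 9.91954429e-02 3.83534732e-03 3.15741687e-02
316.082785 4.02389352e-03 9.63681216e-02 3.31814349e-03 3.06989301e-02
341.890651 3.12365277e-03 9.35615326e-02 2.87797973e-03 3.00361790e-02
369.805707 2.42327740e-03 9.07797230e-02 2.50413761e-03 2.95292725e-02
400.000000 1.87874474e-03 8.80262623e-02 2.18725892e-03 2.91340109e-02
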