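# Photon mass interaction coefficients for Yb (Z=70, A=173.045)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 2.89704087e+02 1.56023098e-01 4.12801754e+00 2.89707015e+02
10.816491 2.70048875e+02 1.55556047e-01 3.81530787e+00 2.70052021e+02
11.699647 2.20820999e+02 1.55054993e-01 3.51407852e+00 2.20824379e+02
12.654913 1.80228665e+02 1.54517802e-01 3.22646922e+00 1.80232295e+02
13.688174 1.46888898e+02 1.53942258e-01 2.95434990e+00 1.46892793e+02
14.805801 1.19568472e+02 1.53326072e-01 2.69908899e+00 1.19572649e+02
16.014681 9.72285311e+01 1.52666888e-01 2.46140382e+00 9.72330082e+01
17.322265 7.89807452e+01 1.51962294e-01 2.24132433e+00 7.89855405e+01
18.736612 6.40832454e+01 1.51209832e-01 2.03827008e+00 6.40883777e+01
19.989500 5.38934668e+01 1.50551503e-01 1.88290605e+00 5.38988916e+01
20.009500 5.37490493e+01 1.50541056e-01 1.88058751e+00 5.37544787e+01
20.266439 5.19394717e+01 1.50407015e-01 1.85121807e+00 5.19449605e+01
21.921175 4.20505085e+01 1.49551343e-01 1.67892285e+00 4.20563736e+01
23.711019 3.40167165e+01 1.48640323e-01 1.52013803e+00 3.40229782e+01
25.647001 2.74971852e+01 1.47671492e-01 1.37246214e+00 2.75038642e+01
27.741055 2.22013317e+01 1.46642441e-01 1.22827497e+00 2.22084486e+01
30.006087 1.79077297e+01 1.45550847e-01 1.09215164e+00 1.79153054e+01
32.456056 1.44371709e+01 1.44394506e-01 9.67217861e-01 1.44452260e+01
35.106063 1.16331111e+01 1.43171361e-01 8.54253441e-01 1.16416659e+01
37.972440 9.36856572e+00 1.41879547e-01 7.52932617e-01 9.37764008e+00
41.072855 7.53840108e+00 1.40517423e-01 6.62464768e-01 7.54801408e+00
44.426415 6.06130703e+00 1.39083621e-01 5.81910283e-01 6.07147682e+00
48.053791 4.86713765e+00 1.37577079e-01 5.10325704e-01 4.87788119e+00
51.977339 3.90631212e+00 1.35997087e-01 4.46822931e-01 3.91764494e+00
56.221240 3.13446366e+00 1.34343327e-01 3.90587380e-01 3.14639960e+00
60.811652 2.51451573e+00 1.32615908e-01 3.40878453e-01 2.52706667e+00
61.322300 2.45612680e+00 1.32427543e-01 3.35938677e-01 2.46874388e+00
61.342300 1.30737607e+01 1.32420180e-01 3.35747373e-01 4.62942491e+00
65.776867 1.09312495e+01 1.30815403e-01 2.97023770e-01 4.35010260e+00
71.147488 8.89416311e+00 1.28942874e-01 2.58412005e-01 3.94754353e+00
76.956614 7.23185993e+00 1.26999900e-01 2.24486547e-01 3.51743107e+00
83.240051 5.86982451e+00 1.24988585e-01 1.94740271e-01 3.08678734e+00
90.036524 4.75592714e+00 1.22911566e-01 1.68711564e-01 2.67565343e+00
97.387922 3.85071037e+00 1.20772006e-01 1.45980836e-01 2.29811308e+00
105.339556 3.11558058e+00 1.18573580e-01 1.26167894e-01 1.95895723e+00
113.940433 2.51899074e+00 1.16320444e-01 1.08929409e-01 1.65933741e+00
123.243564 2.03447589e+00 1.14017193e-01 9.39563048e-02 1.39764068e+00
133.306287 1.63419947e+00 1.11668813e-01 8.09715970e-02 1.16654117e+00
144.190622 1.31321988e+00 1.09280617e-01 6.97280168e-02 9.71176441e-01
155.963653 1.05572084e+00 1.06858171e-01 6.00055422e-02 8.07011529e-01
168.697940 8.49062512e-01 1.04407220e-01 5.16091581e-02 6.69753629e-01
182.471971 6.83139051e-01 1.01933604e-01 4.43666496e-02 5.55475480e-01
197.370639 5.49867032e-01 9.94431700e-02 3.81262544e-02 4.60669048e-01
213.485768 4.42777906e-01 9.69416919e-02 3.27550132e-02 3.82255391e-01
230.916684 3.56693167e-01 9.44347891e-02 2.81361376e-02 3.17568185e-01
249.770817 2.87465323e-01 9.19278538e-02 2.41681934e-02 2.64322604e-01
270.164373 2.31771242e-01 8.94259871e-02 2.07624268e-02 2.20577177e-01
292.223044 1.86947206e-01 8.69339472e-02 1.78424150e-02 1.84693497e-01
316.082785 1.50857203e-01 8.44561096e-02 1.53413228e-02 1.55296749e-01
341.890651 1.21787692e-01 8.19964415e-02 1.32010478e-02 1.31238773e-01
369.805707 9.83635083e-02 7.95584900e-02 1.13727884e-02 1.11564536e-01
400.000000 7.94806114e-02 7.71453830e-02 9.81223763e-03 9.54823575e-02
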