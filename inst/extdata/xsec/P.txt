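# Photon mass interaction coefficients for P (Z=15, A=30.974)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 3.88452534e+01 1.86785809e-01 6.53743310e-01 3.88487581e+01
10.816491 3.08056937e+01 1.86226670e-01 5.94478302e-01 3.08094607e+01
11.699647 2.44095626e+01 1.85626825e-01 5.38017981e-01 2.44136094e+01
12.654913 1.93251800e+01 1.84983717e-01 4.84840320e-01 1.93295251e+01
13.688174 1.52869317e+01 1.84294694e-01 4.35311883e-01 1.52915945e+01
14.805801 1.20822857e+01 1.83557016e-01 3.89654790e-01 1.20872866e+01
16.014681 9.54132618e+00 1.82767862e-01 3.47938200e-01 9.54668602e+00
17.322265 7.52832207e+00 1.81924345e-01 3.10093334e-01 7.53406279e+00
18.736612 5.93494176e+00 1.81023522e-01 2.75945194e-01 5.94108596e+00
19.989500 4.87484280e+00 1.80235392e-01 2.50394217e-01 4.88133720e+00
20.009500 4.86002337e+00 1.80222885e-01 2.50017095e-01 4.86652331e+00
20.266439 4.67479581e+00 1.80062416e-01 2.45251253e-01 4.68136673e+00
21.921175 3.67905174e+00 1.79038033e-01 2.17738283e-01 3.68607320e+00
23.711019 2.89291332e+00 1.77947390e-01 1.93131353e-01 2.90040963e+00
25.647001 2.27279617e+00 1.76787536e-01 1.71082358e-01 2.28079198e+00
27.741055 1.78299742e+00 1.75555589e-01 1.50852444e-01 1.79151757e+00
30.006087 1.39694678e+00 1.74248769e-01 1.32506285e-01 1.40601614e+00
32.456056 1.09383212e+00 1.72864434e-01 1.16074324e-01 1.10347539e+00
35.106063 8.55977801e-01 1.71400125e-01 1.01468607e-01 8.66219337e-01
37.972440 6.69444934e-01 1.69853606e-01 8.85493596e-02 6.80308455e-01
41.072855 5.23247777e-01 1.68222917e-01 7.71597913e-02 5.34756145e-01
44.426415 4.08733174e-01 1.66506415e-01 6.71434783e-02 4.20908117e-01
48.053791 3.19089329e-01 1.64702832e-01 5.83524307e-02 3.31951151e-01
51.977339 2.48957172e-01 1.62811316e-01 5.06503195e-02 2.62524458e-01
56.221240 1.94123087e-01 1.60831488e-01 4.39133050e-02 2.08412402e-01
60.811652 1.51276087e-01 1.58763478e-01 3.80297351e-02 1.66301675e-01
61.322300 1.47304419e-01 1.58537973e-01 3.74489478e-02 1.62409184e-01
61.342300 1.47151649e-01 1.58529159e-01 3.74264707e-02 1.62259504e-01
65.776867 1.17816042e-01 1.56607971e-01 3.28993921e-02 1.33589531e-01
71.147488 9.17023120e-02 1.54366240e-01 2.84325718e-02 1.08232437e-01
76.956614 7.13343422e-02 1.52040175e-01 2.45491673e-02 8.86266884e-02
83.240051 5.54575302e-02 1.49632293e-01 2.11777929e-02 7.35143083e-02
90.036524 4.30890591e-02 1.47145753e-01 1.82549779e-02 6.19089155e-02
97.387922 3.34594981e-02 1.44584341e-01 1.57244095e-02 5.30373725e-02
105.339556 2.59668483e-02 1.41952457e-01 1.35362547e-02 4.62938808e-02
113.940433 2.01404019e-02 1.39255075e-01 1.16465226e-02 4.12038952e-02
123.243564 1.56123388e-02 1.36497698e-01 1.00164641e-02 3.73957772e-02
133.306287 1.20954160e-02 1.33686293e-01 8.61203772e-03 3.45785437e-02
144.190622 9.36545647e-03 1.30827221e-01 7.40340654e-03 3.25244104e-02
155.963653 7.24761157e-03 1.27927147e-01 6.36446502e-03 3.10551071e-02
168.697940 5.60559160e-03 1.24992949e-01 5.47241517e-03 3.00311540e-02
182.471971 4.33322868e-03 1.22031615e-01 4.70738275e-03 2.93434617e-02
197.370639 3.34787071e-03 1.19050148e-01 4.05204858e-03 2.89067534e-02
213.485768 2.58521259e-03 1.16055460e-01 3.49135858e-03 2.86544141e-02
230.916684 1.99525440e-03 1.13054277e-01 3.01219503e-03 2.85344552e-02
249.770817 1.53914304e-03 1.10053055e-01 2.60319256e-03 2.85063539e-02
270.164373 1.18670560e-03 1.07057901e-01 2.25445655e-03 2.85385740e-02
292.223044 9.14524434e-04 1.04074511e-01 1.95745251e-03 2.86066221e-02
316.082785 7.04435714e-04 1.01108124e-01 1.70475057e-03 2.86915217e-02
341.890651 5.42359207e-04 9.81634889e-02 1.48990453e-03 2.87786161e-02
369.805707 4.17386701e-04 9.52448521e-02 1.30743645e-03 2.88566285e-02
400.000000 3.21072412e-04 9.23559585e-02 1.15247906e-03 2.89169274e-02
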