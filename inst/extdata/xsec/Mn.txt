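# Photon mass interaction coefficients for Mn (Z=25, A=54.938)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 1.49804204e+02 1.75516147e-01 1.09959169e+00 1.49807497e+02
10.816491 1.21174538e+02 1.74990744e-01 1.00617961e+00 1.21178078e+02
11.699647 9.78659584e+01 1.74427090e-01 9.20039255e-01 9.78697610e+01
12.654913 7.89160523e+01 1.73822783e-01 8.40566411e-01 7.89201353e+01
13.688174 6.34870391e+01 1.73175333e-01 7.67048754e-01 6.34914206e+01
14.805801 5.09784375e+01 1.72482162e-01 6.98774031e-01 5.09831365e+01
16.014681 4.08814587e+01 1.71740622e-01 6.35119364e-01 4.08864952e+01
17.322265 3.27440319e+01 1.70947998e-01 5.75604052e-01 3.27494262e+01
18.736612 2.61939337e+01 1.70101526e-01 5.19902858e-01 2.61997072e+01
19.989500 2.17698586e+01 1.69360947e-01 4.76700834e-01 2.17759611e+01
20.009500 2.17075799e+01 1.69349195e-01 4.76052411e-01 2.17136876e+01
20.266439 2.09280708e+01 1.69198408e-01 4.67829881e-01 2.09342453e+01
21.921175 1.66999383e+01 1.68235831e-01 4.19306622e-01 1.67065361e+01
23.711019 1.33092984e+01 1.67210991e-01 3.74323946e-01 1.33163425e+01
25.647001 1.05937046e+01 1.66121116e-01 3.32856201e-01 1.06012180e+01
27.741055 8.41943821e+00 1.64963499e-01 2.94750298e-01 8.42744430e+00
30.006087 6.67226253e+00 1.63735525e-01 2.60220136e-01 6.68078469e+00
32.456056 5.28134142e+00 1.62434714e-01 2.29225542e-01 5.29040288e+00
35.106063 4.17806436e+00 1.61058753e-01 2.01553478e-01 4.18768798e+00
37.972440 3.30342107e+00 1.59605543e-01 1.76928221e-01 3.31362914e+00
41.072855 2.61041144e+00 1.58073241e-01 1.55063814e-01 2.62122545e+00
44.426415 2.06162006e+00 1.56460304e-01 1.35686833e-01 2.07306043e+00
48.053791 1.62727692e+00 1.54765539e-01 1.18544555e-01 1.63936272e+00
51.977339 1.28370755e+00 1.52988148e-01 1.03406523e-01 1.29645626e+00
56.221240 1.01209495e+00 1.51127772e-01 9.00634571e-02 1.02552212e+00
60.811652 7.97490958e-01 1.49184534e-01 7.83253690e-02 8.11609981e-01
61.322300 7.77471237e-01 1.48972635e-01 7.71620852e-02 7.91664661e-01
61.342300 7.76700702e-01 1.48964353e-01 7.71170472e-02 7.90897030e-01
65.776867 6.28027317e-01 1.47159079e-01 6.80196865e-02 6.42849117e-01
71.147488 4.94286261e-01 1.45052603e-01 5.89896252e-02 5.09819046e-01
76.956614 3.88798731e-01 1.42866879e-01 5.10928487e-02 4.05047749e-01
83.240051 3.05644480e-01 1.40604276e-01 4.42003574e-02 3.22611808e-01
90.036524 2.40133572e-01 1.38267761e-01 3.81955365e-02 2.57817938e-01
97.387922 1.88552831e-01 1.35860891e-01 3.29732876e-02 2.06949481e-01
105.339556 1.47964111e-01 1.33387801e-01 2.84392203e-02 1.67064718e-01
113.940433 1.16043876e-01 1.30853165e-01 2.45088726e-02 1.35836510e-01
123.243564 9.09557108e-02 1.28262153e-01 2.11069388e-02 1.11424852e-01
133.306287 7.12490493e-02 1.25620373e-01 1.81665160e-02 9.23756647e-02
144.190622 5.57787811e-02 1.22933803e-01 1.56283726e-02 7.75404469e-02
155.963653 4.36414667e-02 1.20208704e-01 1.34402260e-02 6.60125446e-02
168.697940 3.41247591e-02 1.17451539e-01 1.15560614e-02 5.70766130e-02
182.471971 2.66673210e-02 1.14668877e-01 9.93548934e-03 5.01685696e-02
197.370639 2.08270785e-02 1.11867296e-01 8.54313548e-03 4.48438742e-02
213.485768 1.62560922e-02 1.09053290e-01 7.34810709e-03 4.07524168e-02
230.916684 1.26806782e-02 1.06233183e-01 6.32346812e-03 3.76186449e-02
249.770817 9.88569161e-03 1.03413039e-01 5.44583381e-03 3.52258444e-02
270.164373 7.70210839e-03 1.00598596e-01 4.69492598e-03 3.34037105e-02
292.223044 5.99721965e-03 9.77952087e-02 4.05324800e-03 3.20185234e-02
316.082785 4.66689294e-03 9.50077976e-02 3.50568012e-03 3.09653871e-02
341.890651 3.62946897e-03 9.22408262e-02 3.03916890e-03 3.01621003e-02
369.805707 2.82095096e-03 8.94982844e-02 2.64249445e-03 2.95443202e-02
400.000000 2.19121522e-03 8.67836913e-02 2.30586765e-03 2.90617484e-02
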