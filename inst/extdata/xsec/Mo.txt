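# Photon mass interaction coefficients for Mo (Z=42, A=95.95)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 8.20518366e+01 1.68831790e-01 2.26793236e+00 8.20550045e+01
10.816491 6.60351316e+01 1.68326396e-01 2.09831170e+00 6.60385365e+01
11.699647 5.30854448e+01 1.67784208e-01 1.93307409e+00 5.30891026e+01
12.654913 4.26372110e+01 1.67202916e-01 1.77286119e+00 4.26411385e+01
13.688174 3.42181651e+01 1.66580123e-01 1.61861143e+00 3.42223798e+01
14.805801 2.74521101e+01 1.65913351e-01 1.47141331e+00 2.74566302e+01
16.014681 2.20159768e+01 1.65200052e-01 1.33234131e+00 2.20208215e+01
17.322265 1.76495360e+01 1.64437614e-01 1.20230625e+00 1.76547249e+01
18.736612 1.41434336e+01 1.63623379e-01 1.08194387e+00 1.41489872e+01
19.989500 1.17787291e+01 1.62911004e-01 9.90184237e-01 1.17845992e+01
20.009500 8.09213581e+01 1.62899700e-01 9.88820019e-01 3.48254666e+01
20.266439 7.80129261e+01 1.62754655e-01 9.71556485e-01 3.41375373e+01
21.921175 6.30881349e+01 1.61828737e-01 8.71110982e-01 3.02868784e+01
23.711019 5.13459885e+01 1.60842927e-01 7.80283884e-01 2.66669788e+01
25.647001 4.17115585e+01 1.59794559e-01 6.98013694e-01 2.31787544e+01
27.741055 3.38028200e+01 1.58681028e-01 6.20700073e-01 1.99199342e+01
30.006087 2.73380092e+01 1.57499821e-01 5.49287939e-01 1.69602104e+01
32.456056 2.20804299e+01 1.56248550e-01 4.84481560e-01 1.43337780e+01
35.106063 1.78102179e+01 1.54924991e-01 4.26263864e-01 1.20361480e+01
37.972440 1.43465268e+01 1.53527125e-01 3.74283205e-01 1.00494052e+01
41.072855 1.15361137e+01 1.52053179e-01 3.28053781e-01 8.34470789e+00
44.426415 9.25795391e+00 1.50501669e-01 2.87055062e-01 6.89340746e+00
48.053791 7.42154984e+00 1.48871448e-01 2.50778122e-01 5.67258795e+00
51.977339 5.94285174e+00 1.47161747e-01 2.18744995e-01 4.65173358e+00
56.221240 4.75349069e+00 1.45372221e-01 1.90514975e-01 3.80257112e+00
60.811652 3.79791128e+00 1.43502990e-01 1.65685110e-01 3.09954397e+00
61.322300 3.70793108e+00 1.43299161e-01 1.63224612e-01 3.03229098e+00
61.342300 3.70446475e+00 1.43291194e-01 1.63129348e-01 3.02969635e+00
65.776867 3.03101800e+00 1.41554672e-01 1.43888430e-01 2.51997705e+00
71.147488 2.41624532e+00 1.39528419e-01 1.24791438e-01 2.04404294e+00
76.956614 1.92397658e+00 1.37425937e-01 1.08091631e-01 1.65460703e+00
83.240051 1.53007901e+00 1.35249503e-01 9.35151919e-02 1.33685763e+00
90.036524 1.21608284e+00 1.33001971e-01 8.08149258e-02 1.07912408e+00
97.387922 9.66241531e-01 1.30686765e-01 6.97682654e-02 8.70835314e-01
105.339556 7.67503091e-01 1.28307860e-01 6.01755249e-02 7.02818687e-01
113.940433 6.09460131e-01 1.25869752e-01 5.18581631e-02 5.67523103e-01
123.243564 4.83816010e-01 1.23377417e-01 4.46570225e-02 4.58754204e-01
133.306287 3.83958390e-01 1.20836247e-01 3.84307801e-02 3.71446391e-01
144.190622 3.04618663e-01 1.18251992e-01 3.30543638e-02 3.01468583e-01
155.963653 2.41599984e-01 1.15630675e-01 2.84173859e-02 2.45460161e-01
168.697940 1.91560152e-01 1.12978514e-01 2.44227242e-02 2.00693385e-01
182.471971 1.51838310e-01 1.10301827e-01 2.09851733e-02 1.64958696e-01
197.370639 1.20316643e-01 1.07606941e-01 1.80300939e-02 1.36469600e-01
213.485768 9.53100397e-02 1.04900105e-01 1.54923791e-02 1.13784119e-01
230.916684 7.54780770e-02 1.02187398e-01 1.33151006e-02 9.57401918e-02
249.770817 5.97548367e-02 9.94746563e-02 1.14489049e-02 8.14027036e-02
270.164373 4.72929467e-02 9.67673993e-02 9.85075762e-03 7.00201959e-02
292.223044 3.74189803e-02 9.40707758e-02 8.48363184e-03 6.09895735e-02
316.082785 2.95979165e-02 9.13895205e-02 7.31530475e-03 5.38274004e-02
341.890651 2.34048287e-02 8.87279263e-02 6.31788983e-03 4.81466063e-02
369.805707 1.85023372e-02 8.60898316e-02 5.46791602e-03 4.36376207e-02
400.000000 1.46226576e-02 8.34786210e-02 4.74432273e-03 4.00531212e-02
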