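# Photon mass interaction coefficients for Fe (Z=26, A=55.845)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 1.68880009e+02 1.79572143e-01 1.20144613e+00 1.68883378e+02
10.816491 1.36812527e+02 1.79034598e-01 1.09749754e+00 1.36816149e+02
11.699647 1.10663431e+02 1.78457919e-01 1.00174437e+00 1.10667321e+02
12.654913 8.93734844e+01 1.77839648e-01 9.13678522e-01 8.93776617e+01
13.688174 7.20657150e+01 1.77177235e-01 8.32608065e-01 7.20701978e+01
14.805801 5.79813369e+01 1.76468046e-01 7.57764296e-01 5.79861446e+01
16.014681 4.65603182e+01 1.75709369e-01 6.88407798e-01 4.65654710e+01
17.322265 3.73400055e+01 1.74898429e-01 6.23909351e-01 3.73455246e+01
18.736612 2.99085603e+01 1.74032395e-01 5.63791523e-01 2.99144672e+01
19.989500 2.48831778e+01 1.73274703e-01 5.17276123e-01 2.48894214e+01
20.009500 2.48123945e+01 1.73262679e-01 5.16578451e-01 2.48186434e+01
20.266439 2.39263365e+01 1.73108407e-01 5.07732235e-01 2.39326536e+01
21.921175 1.91167279e+01 1.72123586e-01 4.55542483e-01 1.91234782e+01
23.711019 1.52547412e+01 1.71075063e-01 4.07131641e-01 1.52619480e+01
25.647001 1.21575910e+01 1.69960003e-01 3.62400187e-01 1.21652780e+01
27.741055 9.67366390e+00 1.68775634e-01 3.21089424e-01 9.68185499e+00
30.006087 7.68679741e+00 1.67519283e-01 2.83547337e-01 7.69551651e+00
32.456056 6.09472698e+00 1.66188412e-01 2.49808694e-01 6.10399784e+00
35.106063 4.82615512e+00 1.64780654e-01 2.19675686e-01 4.83600113e+00
37.972440 3.81938803e+00 1.63293862e-01 1.92860543e-01 3.82983200e+00
41.072855 3.02085477e+00 1.61726149e-01 1.69054607e-01 3.03191869e+00
44.426415 2.38785357e+00 1.60075939e-01 1.47959142e-01 2.39955831e+00
48.053791 1.88636474e+00 1.58342010e-01 1.29297051e-01 1.89872984e+00
51.977339 1.48930028e+00 1.56523545e-01 1.12815761e-01 1.50234359e+00
56.221240 1.17510343e+00 1.54620178e-01 9.82863684e-02 1.18884089e+00
60.811652 9.26628921e-01 1.52632034e-01 8.55015920e-02 9.41074220e-01
61.322300 9.03437830e-01 1.52415238e-01 8.42343730e-02 9.17959249e-01
61.342300 9.02545190e-01 1.52406764e-01 8.41853112e-02 9.17069580e-01
65.776867 7.30247972e-01 1.50559772e-01 7.42735807e-02 7.45412289e-01
71.147488 5.75133324e-01 1.48404618e-01 6.44319762e-02 5.91025055e-01
76.956614 4.52688403e-01 1.46168385e-01 5.58223101e-02 4.69312919e-01
83.240051 3.56091787e-01 1.43853495e-01 4.83046860e-02 3.73451212e-01
90.036524 2.79933878e-01 1.41462985e-01 4.17526758e-02 2.98026912e-01
97.387922 2.19927288e-01 1.39000495e-01 3.60523240e-02 2.38749065e-01
105.339556 1.72676104e-01 1.36470255e-01 3.11012618e-02 1.92218107e-01
113.940433 1.35492171e-01 1.33877045e-01 2.68078419e-02 1.55742192e-01
123.243564 1.06248897e-01 1.31226158e-01 2.30903043e-02 1.27191060e-01
133.306287 8.32649889e-02 1.28523330e-01 1.98759706e-02 1.04879818e-01
144.190622 6.52120326e-02 1.25774675e-01 1.71004560e-02 8.74765879e-02
155.963653 5.10410918e-02 1.22986602e-01 1.47068961e-02 7.39291421e-02
168.697940 3.99244306e-02 1.20165722e-01 1.26452180e-02 6.34066781e-02
182.471971 3.12092804e-02 1.17318756e-01 1.08714491e-02 5.52536185e-02
197.370639 2.43811824e-02 1.14452433e-01 9.34705425e-03 4.89529814e-02
213.485768 1.90349409e-02 1.11573399e-01 8.03836661e-03 4.40973500e-02
230.916684 1.48516215e-02 1.08688122e-01 6.91600055e-03 4.03658786e-02
249.770817 1.15803486e-02 1.05802807e-01 5.95442744e-03 3.75060861e-02
270.164373 9.02390892e-03 1.02923326e-01 5.13148318e-03 3.53194484e-02
292.223044 7.02737279e-03 1.00055154e-01 4.42803930e-03 3.36500019e-02
316.082785 5.46910736e-03 9.72033293e-02 3.82755741e-03 3.23753324e-02
341.890651 4.25368225e-03 9.43724159e-02 3.31576644e-03 3.13994551e-02
369.805707 3.30627355e-03 9.15664969e-02 2.88043275e-03 3.06471921e-02
400.000000 2.56825231e-03 8.87891723e-02 2.51086372e-03 3.00597357e-02
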