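# Photon mass interaction coefficients for C (Z=6, A=12.011)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 1.96502711e+00 1.92673504e-01 1.62013301e-01 1.96864237e+00
10.816491 1.52527805e+00 1.92096741e-01 1.47701993e-01 1.52916375e+00
11.699647 1.18353357e+00 1.91477988e-01 1.34409287e-01 1.18770791e+00
12.654913 9.18043397e-01 1.90814608e-01 1.22019363e-01 9.22525482e-01
13.688174 7.11863803e-01 1.90103867e-01 1.10445398e-01 7.16673628e-01
14.805801 5.51799972e-01 1.89342936e-01 9.96281154e-02 5.56958414e-01
16.014681 4.27580121e-01 1.88528908e-01 8.95324364e-02 4.33108909e-01
17.322265 3.31210738e-01 1.87658801e-01 8.01425231e-02 3.37132416e-01
18.736612 2.56473436e-01 1.86729584e-01 7.14554039e-02 2.62811303e-01
19.989500 2.07652929e-01 1.85916611e-01 6.48217285e-02 2.14352043e-01
20.009500 2.06976224e-01 1.85903710e-01 6.47230097e-02 2.13681049e-01
20.266439 1.98532433e-01 1.85738182e-01 6.34735421e-02 2.05310472e-01
21.921175 1.53628448e-01 1.84681510e-01 5.61972419e-02 1.60871239e-01
23.711019 1.18840083e-01 1.83556488e-01 4.96182121e-02 1.26572690e-01
25.647001 9.18978586e-02 1.82360074e-01 4.37148736e-02 1.00145704e-01
27.741055 7.09370509e-02 1.81089295e-01 3.84440712e-02 7.97257616e-02
30.006087 5.46733579e-02 1.79741283e-01 3.37527034e-02 6.40285905e-02
32.456056 4.21425182e-02 1.78313312e-01 2.95864928e-02 5.20897631e-02
35.106063 3.24868190e-02 1.76802846e-01 2.58935077e-02 4.30511796e-02
37.972440 2.50458469e-02 1.75207580e-01 2.26257464e-02 3.62517981e-02
41.072855 1.93110526e-02 1.73525489e-01 1.97394408e-02 3.11821778e-02
44.426415 1.48907899e-02 1.71754881e-01 1.71948468e-02 2.74495006e-02
48.053791 1.14834124e-02 1.69894447e-01 1.49558816e-02 2.47506530e-02
51.977339 8.85656900e-03 1.67943309e-01 1.29897643e-02 2.28515107e-02
56.221240 6.83126712e-03 1.65901074e-01 1.12667047e-02 2.15709970e-02
60.811652 5.26960581e-03 1.63767878e-01 9.75964869e-03 2.07688162e-02
61.322300 5.12590792e-03 1.63535265e-01 9.61077895e-03 2.07067921e-02
61.342300 5.12038443e-03 1.63526173e-01 9.60501707e-03 2.07044563e-02
65.776867 4.06533179e-03 1.61544427e-01 8.44406721e-03 2.03360179e-02
71.147488 3.13656850e-03 1.59232035e-01 7.29777787e-03 2.01877408e-02
76.956614 2.42021744e-03 1.56832649e-01 6.30078164e-03 2.02576376e-02
83.240051 1.86764679e-03 1.54348868e-01 5.43511194e-03 2.04935944e-02
90.036524 1.44137101e-03 1.51783949e-01 4.68468813e-03 2.08544501e-02
97.387922 1.11249338e-03 1.49141800e-01 4.03517128e-03 2.13074841e-02
105.339556 8.58735949e-04 1.46426956e-01 3.47382351e-03 2.18264991e-02
113.940433 6.62921890e-04 1.43644549e-01 2.98937025e-03 2.23903597e-02
123.243564 5.11806195e-04 1.40800256e-01 2.57186505e-03 2.29818827e-02
133.306287 3.95174713e-04 1.37900233e-01 2.21256168e-03 2.35869954e-02
144.190622 3.05149845e-04 1.34951040e-01 1.90379108e-03 2.41940996e-02
155.963653 2.35655478e-04 1.31959553e-01 1.63884482e-03 2.47935896e-02
168.697940 1.82004569e-04 1.28932865e-01 1.41186706e-03 2.53774877e-02
182.471971 1.40581250e-04 1.25878187e-01 1.21775263e-03 2.59391644e-02
197.370639 1.08595760e-04 1.22802740e-01 1.05205371e-03 2.64731227e-02
213.485768 8.38955077e-05 1.19713656e-01 9.10894847e-04 2.69748270e-02
230.916684 6.48193884e-05 1.16617872e-01 7.90896592e-04 2.74405652e-02
249.770817 5.00854474e-05 1.13522049e-01 6.89109628e-04 2.78673326e-02
270.164373 3.87042471e-05 1.10432484e-01 6.02958122e-04 2.82527338e-02
292.223044 2.99120491e-05 1.07355055e-01 5.30193272e-04 2.85948952e-02
316.082785 2.31192758e-05 1.04295164e-01 4.68853663e-04 2.88923892e-02
341.890651 1.78707533e-05 1.01257711e-01 4.17232210e-04 2.91441656e-02
369.805707 1.38150392e-05 9.82470751e-02 3.73847643e-04 2.93494932e-02
400.000000 1.06807581e-05 9.52671204e-02 3.37417158e-04 2.95079087e-02
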