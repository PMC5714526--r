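# Photon mass interaction coefficients for Ti (Z=22, A=47.867)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 1.09061513e+02 1.77270465e-01 9.20857862e-01 1.09064839e+02
10.816491 8.76472906e+01 1.76739810e-01 8.47447108e-01 8.76508657e+01
11.699647 7.03462709e+01 1.76170523e-01 7.78654697e-01 7.03501116e+01
12.654913 5.63925380e+01 1.75560176e-01 7.13879859e-01 5.63966618e+01
13.688174 4.51520093e+01 1.74906254e-01 6.52643250e-01 4.51564346e+01
14.805801 3.61080909e+01 1.74206155e-01 5.94624782e-01 3.61128370e+01
16.014681 2.88403937e+01 1.73457203e-01 5.39663438e-01 2.88454805e+01
17.322265 2.30072349e+01 1.72656656e-01 4.87732189e-01 2.30126832e+01
18.736612 1.83312647e+01 1.71801724e-01 4.38900557e-01 1.83370959e+01
19.989500 1.51849677e+01 1.71053743e-01 4.01048450e-01 1.51911313e+01
20.009500 1.51407554e+01 1.71041873e-01 4.00481248e-01 1.51469242e+01
20.266439 1.45875726e+01 1.70889579e-01 3.93292121e-01 1.45938088e+01
21.921175 1.15929009e+01 1.69917381e-01 3.51040667e-01 1.15995647e+01
23.711019 9.20048463e+00 1.68882297e-01 3.12249025e-01 9.20759906e+00
25.647001 7.29506704e+00 1.67781529e-01 2.76923745e-01 7.30265552e+00
27.741055 5.77342414e+00 1.66612341e-01 2.44835703e-01 5.78151024e+00
30.006087 4.56134489e+00 1.65372094e-01 2.15925611e-01 4.56995223e+00
32.456056 3.60140524e+00 1.64058281e-01 1.90036788e-01 3.61055727e+00
35.106063 2.84163893e+00 1.62668567e-01 1.66942461e-01 2.85135874e+00
37.972440 2.24069086e+00 1.61200832e-01 1.46397446e-01 2.25100096e+00
41.072855 1.76567022e+00 1.59653214e-01 1.28161609e-01 1.77659233e+00
44.426415 1.39043414e+00 1.58024155e-01 1.12009228e-01 1.40198886e+00
48.053791 1.09421614e+00 1.56312451e-01 9.77318079e-02 1.10642274e+00
51.977339 8.60530881e-01 1.54517294e-01 8.51380659e-02 8.73407015e-01
56.221240 6.76299930e-01 1.52638323e-01 7.40529444e-02 6.89861311e-01
60.811652 5.31154341e-01 1.50675663e-01 6.43164084e-02 5.45414486e-01
61.322300 5.17636956e-01 1.50461645e-01 6.33523827e-02 5.31972247e-01
61.342300 5.17116775e-01 1.50453280e-01 6.33150638e-02 5.31454998e-01
65.776867 4.16878687e-01 1.48629963e-01 5.57823408e-02 4.31848634e-01
71.147488 3.26968073e-01 1.46502432e-01 4.83175784e-02 3.42656111e-01
76.956614 2.56275391e-01 1.44294862e-01 4.18010796e-02 2.72686821e-01
83.240051 2.00730624e-01 1.42009644e-01 3.61231813e-02 2.17867544e-01
90.036524 1.57117612e-01 1.39649774e-01 3.11848867e-02 1.74978737e-01
97.387922 1.22896639e-01 1.37218847e-01 2.68971735e-02 1.41477167e-01
105.339556 9.60635175e-02 1.34721038e-01 2.31803067e-02 1.15355039e-01
113.940433 7.50377508e-02 1.32161068e-01 1.99631472e-02 9.50282162e-02
123.243564 5.85738162e-02 1.29544158e-01 1.71824551e-02 7.92475510e-02
133.306287 4.56908474e-02 1.26875974e-01 1.47822123e-02 6.70286275e-02
144.190622 3.56169330e-02 1.24162550e-01 1.27129574e-02 5.75961109e-02
155.963653 2.77450245e-02 1.21410213e-01 1.09311431e-02 5.03397057e-02
168.697940 2.15980579e-02 1.18625490e-01 9.39853546e-03 4.47793201e-02
182.471971 1.68013829e-02 1.15815015e-01 8.08165515e-03 4.05375311e-02
197.370639 1.30609834e-02 1.12985431e-01 6.95126049e-03 3.73178316e-02
213.485768 1.01462848e-02 1.10143299e-01 5.98189189e-03 3.48874549e-02
230.916684 7.87659253e-03 1.07295004e-01 5.15142879e-03 3.30638190e-02
249.770817 6.11040129e-03 1.04446672e-01 4.44071900e-03 3.17038339e-02
270.164373 4.73697395e-03 1.01604099e-01 3.83318770e-03 3.06954686e-02
292.223044 3.66971281e-03 9.87726909e-02 3.31452628e-03 2.99511046e-02
316.082785 2.84094556e-03 9.59574191e-02 2.87235809e-03 2.94022983e-02
341.890651 2.19782670e-03 9.31627912e-02 2.49598767e-03 2.89956568e-02
369.805707 1.69911843e-03 9.03928372e-02 2.17621782e-03 2.86895930e-02
400.000000 1.31266380e-03 8.76511112e-02 1.90506307e-03 2.84517732e-02
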