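# Photon mass interaction coefficients for Ar (Z=18, A=39.948)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 6.16231817e+01 1.73791038e-01 7.40879427e-01 6.16264426e+01
10.816491 4.91921935e+01 1.73270799e-01 6.80787424e-01 4.91956984e+01
11.699647 3.92244665e+01 1.72712685e-01 6.22867940e-01 3.92282318e+01
12.654913 3.12408929e+01 1.72114318e-01 5.67233648e-01 3.12449357e+01
13.688174 2.48539250e+01 1.71473231e-01 5.14106858e-01 2.48582635e+01
14.805801 1.97316091e+01 1.70786873e-01 4.63774680e-01 1.97362620e+01
16.014681 1.56481821e+01 1.70052622e-01 4.16538909e-01 1.56531691e+01
17.322265 1.23992863e+01 1.69267788e-01 3.72665511e-01 1.24046277e+01
18.736612 9.81656229e+00 1.68429636e-01 3.32341441e-01 9.82227903e+00
19.989500 8.09142867e+00 1.67696336e-01 3.01817367e-01 8.09747125e+00
20.009500 8.06726760e+00 1.67684699e-01 3.01365154e-01 8.07331533e+00
20.266439 7.76516566e+00 1.67535394e-01 2.95646970e-01 7.77127943e+00
21.921175 6.13718600e+00 1.66582278e-01 2.62548903e-01 6.14371898e+00
23.711019 4.84634007e+00 1.65567511e-01 2.32913724e-01 4.85331486e+00
25.647001 3.82369616e+00 1.64488349e-01 2.06439232e-01 3.83113569e+00
27.741055 3.01419311e+00 1.63342109e-01 1.82299835e-01 3.02212051e+00
30.006087 2.37397588e+00 1.62126205e-01 1.60451852e-01 2.38241428e+00
32.456056 1.86811698e+00 1.60838179e-01 1.40861645e-01 1.87708937e+00
35.106063 1.46876844e+00 1.59475742e-01 1.23401543e-01 1.47829747e+00
37.972440 1.15378034e+00 1.58036816e-01 1.07904821e-01 1.16388808e+00
41.072855 9.05550336e-01 1.56519574e-01 9.41939403e-02 9.16258063e-01
44.426415 7.10102276e-01 1.54922490e-01 8.20944475e-02 7.21430203e-01
48.053791 5.56349001e-01 1.53244383e-01 7.14413030e-02 5.68316020e-01
51.977339 4.35502979e-01 1.51484461e-01 6.20814151e-02 4.48126383e-01
56.221240 3.40605552e-01 1.49642370e-01 5.38743033e-02 3.53900753e-01
60.811652 2.66151246e-01 1.47718232e-01 4.66918910e-02 2.80131497e-01
61.322300 2.59234462e-01 1.47508416e-01 4.59821482e-02 2.73288382e-01
61.342300 2.58968353e-01 1.47500215e-01 4.59546775e-02 2.73025148e-01
65.776867 2.07788225e-01 1.45712685e-01 4.04179449e-02 2.22464345e-01
71.147488 1.62079658e-01 1.43626913e-01 3.49473716e-02 1.77459774e-01
76.956614 1.26313793e-01 1.41462673e-01 3.01854712e-02 1.42403103e-01
83.240051 9.83529294e-02 1.39222308e-01 2.60471976e-02 1.15153489e-01
90.036524 7.65134335e-02 1.36908758e-01 2.24564398e-02 9.40239842e-02
97.387922 5.94704993e-02 1.34525545e-01 1.93453038e-02 7.76863324e-02
105.339556 4.61826281e-02 1.32076762e-01 1.66534370e-02 6.50955000e-02
113.940433 3.58317942e-02 1.29567038e-01 1.43273699e-02 5.54298909e-02
123.243564 2.77760848e-02 1.27001493e-01 1.23198680e-02 4.80440398e-02
133.306287 2.15122482e-02 1.24385679e-01 1.05893426e-02 4.24312148e-02
144.190622 1.66461046e-02 1.21725514e-01 9.09928177e-03 3.81938798e-02
155.963653 1.28691912e-02 1.19027199e-01 7.81770712e-03 3.50203888e-02
168.697940 9.94034583e-03 1.16297134e-01 6.71668427e-03 3.26666111e-02
182.471971 7.67119707e-03 1.13541822e-01 5.77186655e-03 3.09414571e-02
197.370639 5.91474474e-03 1.10767777e-01 4.96206086e-03 2.96954847e-02
213.485768 4.55637988e-03 1.07981430e-01 4.26887064e-03 2.88119355e-02
230.916684 3.50683019e-03 1.05189041e-01 3.67629672e-03 2.81996871e-02
249.770817 2.69662336e-03 1.02396615e-01 3.17048754e-03 2.77877134e-02
270.164373 2.07174575e-03 9.96098352e-02 2.73939053e-03 2.75207326e-02
292.223044 1.59024156e-03 9.68340014e-02 2.37258492e-03 2.73557877e-02
316.082785 1.21955139e-03 9.40739871e-02 2.06097978e-03 2.72595635e-02
341.890651 9.34431270e-04 9.13342116e-02 1.79666153e-03 2.72062793e-02
369.805707 7.15327249e-04 8.86186257e-02 1.57285983e-03 2.71760385e-02
400.000000 5.47106944e-04 8.59307137e-02 1.38355807e-03 2.71535357e-02
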