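# Photon mass interaction coefficients for N (Z=7, A=14.007)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 3.38305850e+00 1.92753745e-01 2.03056361e-01 3.38667526e+00
10.816491 2.63373433e+00 1.92176741e-01 1.84011839e-01 2.63762165e+00
11.699647 2.04950985e+00 1.91557730e-01 1.66644711e-01 2.05368593e+00
12.654913 1.59419391e+00 1.90894074e-01 1.50749827e-01 1.59867786e+00
13.688174 1.23950245e+00 1.90183037e-01 1.36156660e-01 1.24431427e+00
14.805801 9.63318067e-01 1.89421790e-01 1.22728156e-01 9.68478657e-01
16.014681 7.48355668e-01 1.88607422e-01 1.10356516e-01 7.53886759e-01
17.322265 5.81115406e-01 1.87736954e-01 9.89582069e-02 5.87039550e-01
18.736612 4.51058306e-01 1.86807349e-01 8.84689290e-02 4.57398812e-01
19.989500 3.65892279e-01 1.85994037e-01 8.04665564e-02 3.72594183e-01
20.009500 3.64710444e-01 1.85981131e-01 8.03473745e-02 3.71418061e-01
20.266439 3.49960406e-01 1.85815535e-01 7.88384730e-02 3.56741267e-01
21.921175 2.71407002e-01 1.84758422e-01 7.00253773e-02 2.78652809e-01
23.711019 2.10396775e-01 1.83632932e-01 6.19918005e-02 2.18132603e-01
25.647001 1.63032051e-01 1.82436020e-01 5.47015378e-02 1.71283331e-01
27.741055 1.26123322e-01 1.81164711e-01 4.81430659e-02 1.34915692e-01
30.006087 9.74313240e-02 1.79816138e-01 4.22899750e-02 1.06790453e-01
32.456056 7.52624788e-02 1.78387572e-01 3.70897673e-02 8.52138663e-02
35.106063 5.81346418e-02 1.76876477e-01 3.24820685e-02 6.87034020e-02
37.972440 4.49022308e-02 1.75280546e-01 2.84069539e-02 5.61128488e-02
41.072855 3.46798445e-02 1.73597755e-01 2.48083983e-02 4.65559136e-02
44.426415 2.67832052e-02 1.71826410e-01 2.16353624e-02 3.93471461e-02
48.053791 2.06834996e-02 1.69965201e-01 1.88418137e-02 3.39562655e-02
51.977339 1.59720790e-02 1.68013251e-01 1.63863551e-02 2.99728491e-02
56.221240 1.23331703e-02 1.65970165e-01 1.42317425e-02 2.70790386e-02
60.811652 9.52278007e-03 1.63836081e-01 1.23444393e-02 2.50284453e-02
61.322300 9.26395605e-03 1.63603371e-01 1.21578394e-02 2.48513290e-02
61.342300 9.25400652e-03 1.63594275e-01 1.21506172e-02 2.48445685e-02
65.776867 7.35238832e-03 1.61611704e-01 1.06942237e-02 2.36298505e-02
71.147488 5.67634373e-03 1.59298348e-01 9.25387122e-03 2.27346172e-02
76.956614 4.38212157e-03 1.56897963e-01 7.99888213e-03 2.22269703e-02
83.240051 3.38279412e-03 1.54413148e-01 6.90725076e-03 2.20164987e-02
90.036524 2.61121152e-03 1.51847161e-01 5.95926371e-03 2.20323753e-02
97.387922 2.01550469e-03 1.49203911e-01 5.13730836e-03 2.22189058e-02
105.339556 1.55561024e-03 1.46487936e-01 4.42570151e-03 2.25321056e-02
113.940433 1.20058508e-03 1.43704371e-01 3.81052181e-03 2.29370715e-02
123.243564 9.26531545e-04 1.40858893e-01 3.27945169e-03 2.34059659e-02
133.306287 7.14994271e-04 1.37957663e-01 2.82162852e-03 2.39164734e-02
144.190622 5.51721571e-04 1.35007242e-01 2.42750061e-03 2.44506200e-02
155.963653 4.25708566e-04 1.32014508e-01 2.08869347e-03 2.49938701e-02
168.697940 3.28457979e-04 1.28986560e-01 1.79788321e-03 2.55344340e-02
182.471971 2.53409116e-04 1.25930610e-01 1.54867974e-03 2.60627363e-02
197.370639 1.95496790e-04 1.22853883e-01 1.33551596e-03 2.65710035e-02
213.485768 1.50810648e-04 1.19763512e-01 1.15354588e-03 2.70529411e-02
230.916684 1.16332045e-04 1.16666439e-01 9.98552241e-04 2.75034787e-02
249.770817 8.97308359e-05 1.13569326e-01 8.66859420e-04 2.79185627e-02
270.164373 6.92084421e-05 1.10478475e-01 7.55257556e-04 2.82949879e-02
292.223044 5.33766687e-05 1.07399764e-01 6.60936213e-04 2.86302560e-02
316.082785 4.11641279e-05 1.04338598e-01 5.81430022e-04 2.89224569e-02
341.890651 3.17439865e-05 1.01299880e-01 5.14576292e-04 2.91701688e-02
369.805707 2.44781814e-05 9.82879910e-02 4.58480876e-04 2.93723734e-02
400.000000 1.88743504e-05 9.53067952e-02 4.11497487e-04 2.95283867e-02
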