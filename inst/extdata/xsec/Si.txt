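# Photon mass interaction coefficients for Si (Z=14, A=28.085)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 3.24082596e+01 1.92266456e-01 6.22403303e-01 3.24118672e+01
10.816491 2.56485527e+01 1.91690911e-01 5.63459103e-01 2.56524301e+01
11.699647 2.02831962e+01 1.91073465e-01 5.07991399e-01 2.02873617e+01
12.654913 1.60278393e+01 1.90411487e-01 4.56380024e-01 1.60323120e+01
13.688174 1.26554447e+01 1.89702247e-01 4.08835082e-01 1.26602444e+01
14.805801 9.98487326e+00 1.88942924e-01 3.65399807e-01 9.99002081e+00
16.014681 7.87171509e+00 1.88130615e-01 3.25976522e-01 7.87723220e+00
17.322265 6.20093061e+00 1.87262347e-01 2.90366358e-01 6.20683978e+00
18.736612 4.88094787e+00 1.86335092e-01 2.58312210e-01 4.88727235e+00
19.989500 4.00422368e+00 1.85523837e-01 2.34356021e-01 4.01090864e+00
20.009500 3.99197717e+00 1.85510963e-01 2.34002575e-01 3.99866783e+00
20.266439 3.83893205e+00 1.85345786e-01 2.29536258e-01 3.84569577e+00
21.921175 3.01699689e+00 1.84291346e-01 2.03766686e-01 3.02422438e+00
23.711019 2.36917295e+00 1.83168700e-01 1.80751714e-01 2.37688922e+00
25.647001 1.85898320e+00 1.81974814e-01 1.60161239e-01 1.86721362e+00
27.741055 1.45716144e+00 1.80706720e-01 1.41207416e-01 1.46593158e+00
30.006087 1.14107098e+00 1.79361555e-01 1.23987722e-01 1.15040645e+00
32.456056 8.92907561e-01 1.77936602e-01 1.08562915e-01 9.02833791e-01
35.106063 6.98214185e-01 1.76429327e-01 9.48617504e-02 7.08756227e-01
37.972440 5.45580410e-01 1.74837430e-01 8.27546054e-02 5.56762687e-01
41.072855 4.26006802e-01 1.73158893e-01 7.20919791e-02 4.37852848e-01
44.426415 3.32400619e-01 1.71392026e-01 6.27236785e-02 3.44932798e-01
48.053791 2.59175905e-01 1.69535522e-01 5.45076624e-02 2.72415117e-01
51.977339 2.01936602e-01 1.67588506e-01 4.73135391e-02 2.15901978e-01
56.221240 1.57225622e-01 1.65550586e-01 4.10234037e-02 1.71934212e-01
60.811652 1.22326295e-01 1.63421896e-01 3.55314603e-02 1.37792761e-01
61.322300 1.19093487e-01 1.63189775e-01 3.49893773e-02 1.34641454e-01
61.342300 1.18969145e-01 1.63180702e-01 3.49683977e-02 1.34520294e-01
65.776867 9.51053696e-02 1.61203143e-01 3.07431597e-02 1.11341682e-01
71.147488 7.38889682e-02 1.58895636e-01 2.65741902e-02 9.09041176e-02
76.956614 5.73646407e-02 1.56501319e-01 2.29494828e-02 7.51643769e-02
83.240051 4.45040947e-02 1.54022786e-01 1.98022967e-02 6.30906926e-02
90.036524 3.45022751e-02 1.51463285e-01 1.70733947e-02 5.38743415e-02
97.387922 2.67293729e-02 1.48826717e-01 1.47102774e-02 4.68816990e-02
105.339556 2.06930467e-02 1.46117609e-01 1.26665215e-02 4.16165126e-02
113.940433 1.60087074e-02 1.43341081e-01 1.09011614e-02 3.76902431e-02
123.243564 1.23761610e-02 1.40502797e-01 9.37811245e-03 3.47987665e-02
133.306287 9.56126551e-03 1.37608900e-01 8.06566888e-03 3.27040904e-02
144.190622 7.38153391e-03 1.34665938e-01 6.93602789e-03 3.12200150e-02
155.963653 5.69484558e-03 1.31680770e-01 5.96484614e-03 3.02008978e-02
168.697940 4.39059999e-03 1.28660477e-01 5.13084675e-03 2.95328543e-02
182.471971 3.38279050e-03 1.25612252e-01 4.41546188e-03 2.91268707e-02
197.370639 2.60458546e-03 1.22543303e-01 3.80249480e-03 2.89134138e-02
213.485768 2.00409187e-03 1.19460745e-01 3.27786010e-03 2.88382127e-02
230.916684 1.54104618e-03 1.16371501e-01 2.82927636e-03 2.88589570e-02
249.770817 1.18423118e-03 1.13282218e-01 2.44611604e-03 2.89427107e-02
270.164373 9.09461379e-04 1.10199181e-01 2.11913327e-03 2.90638850e-02
292.223044 6.98012852e-04 1.07128253e-01 1.84037458e-03 2.92026487e-02
316.082785 5.35400514e-04 1.04074826e-01 1.60292038e-03 2.93436802e-02
341.890651 4.10426659e-04 1.01043790e-01 1.40077523e-03 2.94751883e-02
369.805707 3.14441151e-04 9.80395150e-02 1.22887846e-03 2.95881438e-02
400.000000 2.40766631e-04 9.50658559e-02 1.08273021e-03 2.96756777e-02
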