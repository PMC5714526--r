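# Photon mass interaction coefficients for S (Z=16, A=32.06)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 4.85306322e+01 1.92489204e-01 7.22868602e-01 4.85342440e+01
10.816491 3.85994052e+01 1.91912993e-01 6.60140234e-01 3.86032871e+01
11.699647 3.06360122e+01 1.91294831e-01 5.99848325e-01 3.06401826e+01
12.654913 2.42943443e+01 1.90632086e-01 5.42470298e-01 2.42988221e+01
13.688174 1.92485485e+01 1.89922025e-01 4.88452538e-01 1.92533537e+01
14.805801 1.52373438e+01 1.89161822e-01 4.38153855e-01 1.52424973e+01
16.014681 1.20514069e+01 1.88348572e-01 3.91804211e-01 1.20569304e+01
17.322265 9.52318527e+00 1.87479298e-01 3.49486130e-01 9.52910129e+00
18.736612 7.51868011e+00 1.86550969e-01 3.11140649e-01 7.52501191e+00
19.989500 6.18306622e+00 1.85738774e-01 2.82385131e-01 6.18975893e+00
20.009500 6.16438237e+00 1.85725885e-01 2.81960430e-01 6.17108078e+00
20.266439 5.93082117e+00 1.85560516e-01 2.76592769e-01 5.93759273e+00
21.921175 4.67413151e+00 1.84504855e-01 2.45587423e-01 4.68136738e+00
23.711019 3.68043368e+00 1.83380909e-01 2.17826796e-01 3.68815889e+00
25.647001 2.89539744e+00 1.82185640e-01 1.92921861e-01 2.90363739e+00
27.741055 2.27440121e+00 1.80916076e-01 1.70144488e-01 2.28318151e+00
30.006087 1.78426639e+00 1.79569353e-01 1.49524753e-01 1.79361268e+00
32.456056 1.39891908e+00 1.78142749e-01 1.31058850e-01 1.40885681e+00
35.106063 1.09613554e+00 1.76633727e-01 1.14633895e-01 1.10668980e+00
37.972440 8.58367617e-01 1.75039987e-01 1.00090269e-01 8.69562849e-01
41.072855 6.71766834e-01 1.73359505e-01 8.72540995e-02 6.83626604e-01
44.426415 5.25410624e-01 1.71590591e-01 7.59534377e-02 5.37957322e-01
48.053791 4.10689121e-01 1.69731936e-01 6.60257491e-02 4.23943671e-01
51.977339 3.20819461e-01 1.67782665e-01 5.73209163e-02 3.34801016e-01
56.221240 2.50461260e-01 1.65742383e-01 4.97020233e-02 2.65186890e-01
60.811652 1.95412365e-01 1.63611228e-01 4.30450805e-02 2.10896750e-01
61.322300 1.90305873e-01 1.63378837e-01 4.23878066e-02 2.05871853e-01
61.342300 1.90109437e-01 1.63369754e-01 4.23623689e-02 2.05678603e-01
65.776867 1.52368258e-01 1.61389903e-01 3.72383223e-02 1.68623380e-01
71.147488 1.18731886e-01 1.59079723e-01 3.21813314e-02 1.35766748e-01
76.956614 9.24634563e-02 1.56682632e-01 2.77841438e-02 1.10283814e-01
83.240051 7.19618516e-02 1.54201228e-01 2.39663839e-02 9.05699828e-02
90.036524 5.59710679e-02 1.51638762e-01 2.06564394e-02 7.53655775e-02
97.387922 4.35064429e-02 1.48999139e-01 1.77906768e-02 6.36821163e-02
105.339556 3.37965208e-02 1.46286892e-01 1.53127175e-02 5.47442275e-02
113.940433 2.62372677e-02 1.43507147e-01 1.31727525e-02 4.79439224e-02
123.243564 2.03560364e-02 1.40665575e-01 1.13268851e-02 4.28046194e-02
133.306287 1.57832225e-02 1.37768326e-01 9.73654223e-03 3.89528593e-02
144.190622 1.22299834e-02 1.34821954e-01 8.36791133e-03 3.60960824e-02
155.963653 9.47073573e-03 1.31833328e-01 7.19141422e-03 3.40051792e-02
168.697940 7.32941283e-03 1.28809535e-01 6.18123353e-03 3.25007955e-02
182.471971 5.66868418e-03 1.25757779e-01 5.31487396e-03 3.14425900e-02
197.370639 4.38150162e-03 1.22685275e-01 4.57275081e-03 3.07208099e-02
213.485768 3.38447559e-03 1.19599145e-01 3.93785118e-03 3.02496849e-02
230.916684 2.61268816e-03 1.16506323e-01 3.39536475e-03 2.99622479e-02
249.770817 2.01563394e-03 1.13413460e-01 2.93245602e-03 2.98062728e-02
270.164373 1.55404570e-03 1.10326851e-01 2.53795186e-03 2.97410874e-02
292.223044 1.19741340e-03 1.07252365e-01 2.20219569e-03 2.97350730e-02
316.082785 9.22046531e-04 1.04195401e-01 1.91677975e-03 2.97637018e-02
341.890651 7.09561712e-04 1.01160854e-01 1.67440523e-03 2.98079961e-02
369.805707 5.45703016e-04 9.81530979e-02 1.46884042e-03 2.98533204e-02
400.000000 4.19422420e-04 9.51759937e-02 1.29456444e-03 2.98884351e-02
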