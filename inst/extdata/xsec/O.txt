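# Photon mass interaction coefficients for O (Z=8, A=15.999)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 5.35356332e+00 1.92862176e-01 2.56496887e-01 5.35718211e+00
10.816491 4.17882581e+00 1.92284847e-01 2.30988681e-01 4.18271532e+00
11.699647 3.26014976e+00 1.91665488e-01 2.07961997e-01 3.26432819e+00
12.654913 2.54220202e+00 1.91001459e-01 1.87165153e-01 2.54668849e+00
13.688174 1.98139771e+00 1.90290022e-01 1.68351727e-01 1.98621224e+00
14.805801 1.54355540e+00 1.89528346e-01 1.51292004e-01 1.54871889e+00
16.014681 1.20188147e+00 1.88713520e-01 1.35782347e-01 1.20741567e+00
17.322265 9.35383738e-01 1.87842562e-01 1.21650200e-01 9.41311215e-01
18.736612 7.27623398e-01 1.86912434e-01 1.08754543e-01 7.33967471e-01
19.989500 5.91271920e-01 1.86098665e-01 9.89696141e-02 5.97977593e-01
20.009500 5.89377844e-01 1.86085752e-01 9.88241570e-02 5.96089234e-01
20.266439 5.65733741e-01 1.85920062e-01 9.69831653e-02 5.72518417e-01
21.921175 4.39648928e-01 1.84862355e-01 8.62483261e-02 4.46898811e-01
23.711019 3.41498187e-01 1.83736232e-01 7.64816123e-02 3.49238366e-01
25.647001 2.65130185e-01 1.82538646e-01 6.76164086e-02 2.73386107e-01
27.741055 2.05479816e-01 1.81266623e-01 5.95584454e-02 2.14277133e-01
30.006087 1.59006340e-01 1.79917290e-01 5.23219996e-02 1.68370733e-01
32.456056 1.23031247e-01 1.78487922e-01 4.58794091e-02 1.32988233e-01
35.106063 9.51857504e-02 1.76975977e-01 4.01710811e-02 1.05760456e-01
37.972440 7.36349159e-02 1.75379148e-01 3.51273146e-02 8.48518403e-02
41.072855 5.69574883e-02 1.73695410e-01 3.06786223e-02 6.88402380e-02
44.426415 4.40527353e-02 1.71923068e-01 2.67601052e-02 5.66237439e-02
48.053791 3.40682476e-02 1.70060812e-01 2.33128718e-02 4.73484799e-02
51.977339 2.63439828e-02 1.68107764e-01 2.02841293e-02 4.03526287e-02
56.221240 2.03689041e-02 1.66063529e-01 1.76267291e-02 3.51230675e-02
60.811652 1.57473819e-02 1.63928244e-01 1.52985677e-02 3.12617696e-02
61.322300 1.53214057e-02 1.63695403e-01 1.50683318e-02 3.09175471e-02
61.342300 1.53050294e-02 1.63686303e-01 1.50594198e-02 3.09043615e-02
65.776867 1.21731623e-02 1.61702616e-01 1.32620033e-02 2.84597811e-02
71.147488 9.40920029e-03 1.59387959e-01 1.14833468e-02 2.64770696e-02
76.956614 7.27203849e-03 1.56986224e-01 9.93243070e-03 2.51269255e-02
83.240051 5.61970727e-03 1.54500011e-01 8.58225377e-03 2.42638940e-02
90.036524 4.34235387e-03 1.51932581e-01 7.40867525e-03 2.37744428e-02
97.387922 3.35498558e-03 1.49287843e-01 6.39015135e-03 2.35697518e-02
105.339556 2.59185066e-03 1.46570341e-01 5.50749992e-03 2.35801460e-02
113.940433 2.00208778e-03 1.43785210e-01 4.74368694e-03 2.37508017e-02
123.243564 1.54635798e-03 1.40938131e-01 4.08362588e-03 2.40384378e-02
133.306287 1.19423756e-03 1.38035269e-01 3.51399546e-03 2.44087684e-02
144.190622 9.22200062e-04 1.35083188e-01 3.02306633e-03 2.48345425e-02
155.963653 7.12054605e-04 1.32088771e-01 2.60053884e-03 2.52940366e-02
168.697940 5.49737270e-04 1.29059119e-01 2.23739289e-03 2.57698925e-02
182.471971 4.24375988e-04 1.26001450e-01 1.92574864e-03 2.62482219e-02
197.370639 3.27567029e-04 1.22922992e-01 1.65873522e-03 2.67179109e-02
213.485768 2.52815296e-04 1.19830883e-01 1.43037473e-03 2.71700792e-02
230.916684 1.95101377e-04 1.16732068e-01 1.23546513e-03 2.75976542e-02
249.770817 1.50546683e-04 1.13633212e-01 1.06948870e-03 2.79950333e-02
270.164373 1.16154482e-04 1.10540623e-01 9.28510616e-04 2.83578120e-02
292.223044 8.96096416e-05 1.07460180e-01 8.09108740e-04 2.86825644e-02
316.082785 6.91237940e-05 1.04397293e-01 7.08289465e-04 2.89666633e-02
341.890651 5.33156285e-05 1.01356865e-01 6.23431469e-04 2.92081318e-02
369.805707 4.11183547e-05 9.83432814e-02 5.52251628e-04 2.94055228e-02
400.000000 3.17081751e-05 9.53604087e-02 4.92727752e-04 2.95578206e-02
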