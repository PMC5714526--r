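# Photon mass interaction coefficients for H (Z=1, A=1.008)
# Generated by tools/make_xsec_tables.py (see header there for method):
# photoelectric from Cromer-Liberman f''; incoherent from free-electron
# Klein-Nishina; coherent from IT92 atomic form factors; mu_en from local
# photoelectric deposition plus the Klein-Nishina energy-transfer integral.
# columns: energy_keV mu_pe mu_incoh mu_coh mu_en   (all cm^2/g)
10.000000 0.00000000e+00 3.82639130e-01 3.20403544e-02 7.17969834e-03
10.816491 0.00000000e+00 3.81493710e-01 2.78621684e-02 7.71679066e-03
11.699647 0.00000000e+00 3.80264899e-01 2.41874203e-02 8.29001937e-03
12.654913 0.00000000e+00 3.78947463e-01 2.09635069e-02 8.90117899e-03
13.688174 0.00000000e+00 3.77535969e-01 1.81420071e-02 9.55205116e-03
14.805801 0.00000000e+00 3.76024803e-01 1.56784207e-02 1.02443850e-02
16.014681 0.00000000e+00 3.74408186e-01 1.35320496e-02 1.09798742e-02
17.322265 0.00000000e+00 3.72680202e-01 1.16658901e-02 1.17601315e-02
18.736612 0.00000000e+00 3.70834826e-01 1.00464787e-02 1.25866595e-02
19.989500 0.00000000e+00 3.69220306e-01 8.87517456e-03 1.33040762e-02
20.009500 0.00000000e+00 3.69194685e-01 8.85815100e-03 1.33154179e-02
20.266439 0.00000000e+00 3.68865957e-01 8.64369237e-03 1.34608182e-02
21.921175 0.00000000e+00 3.66767463e-01 7.43053565e-03 1.43837895e-02
23.711019 0.00000000e+00 3.64533231e-01 6.38292369e-03 1.53565390e-02
25.647001 0.00000000e+00 3.62157218e-01 5.47944372e-03 1.63797746e-02
27.741055 0.00000000e+00 3.59633519e-01 4.70105282e-03 1.74539029e-02
30.006087 0.00000000e+00 3.56956440e-01 4.03115880e-03 1.85789846e-02
32.456056 0.00000000e+00 3.54120568e-01 3.45520137e-03 1.97546888e-02
35.106063 0.00000000e+00 3.51120864e-01 2.96042276e-03 2.09802473e-02
37.972440 0.00000000e+00 3.47952751e-01 2.53568772e-03 2.22544113e-02
41.072855 0.00000000e+00 3.44612210e-01 2.17130751e-03 2.35754108e-02
44.426415 0.00000000e+00 3.41095879e-01 1.85887542e-03 2.49409184e-02
48.053791 0.00000000e+00 3.37401158e-01 1.59111269e-03 2.63480203e-02
51.977339 0.00000000e+00 3.33526304e-01 1.36172976e-03 2.77931952e-02
56.221240 0.00000000e+00 3.29470536e-01 1.16530047e-03 2.92723041e-02
60.811652 0.00000000e+00 3.25234124e-01 9.97150054e-04 3.07805913e-02
61.322300 0.00000000e+00 3.24772167e-01 9.80729903e-04 3.09427909e-02
61.342300 0.00000000e+00 3.24754111e-01 9.80095071e-04 3.09491215e-02
65.776867 0.00000000e+00 3.20818471e-01 8.53255974e-04 3.23127003e-02
71.147488 0.00000000e+00 3.16226186e-01 7.30160967e-04 3.38627035e-02
76.956614 0.00000000e+00 3.11461136e-01 6.24895872e-04 3.54241490e-02
83.240051 0.00000000e+00 3.06528482e-01 5.34913479e-04 3.69901219e-02
90.036524 0.00000000e+00 3.01434692e-01 4.58030112e-04 3.85533222e-02
97.387922 0.00000000e+00 2.96187525e-01 3.92375236e-04 4.01061563e-02
105.339556 0.00000000e+00 2.90795993e-01 3.36347820e-04 4.16408404e-02
113.940433 0.00000000e+00 2.85270284e-01 2.88578805e-04 4.31495132e-02
123.243564 0.00000000e+00 2.79621672e-01 2.47898170e-04 4.46243534e-02
133.306287 0.00000000e+00 2.73862384e-01 2.13306944e-04 4.60576982e-02
144.190622 0.00000000e+00 2.68005447e-01 1.83952820e-04 4.74421586e-02
155.963653 0.00000000e+00 2.62064515e-01 1.59108750e-04 4.87707254e-02
168.697940 0.00000000e+00 2.56053677e-01 1.38154585e-04 5.00368631e-02
182.471971 0.00000000e+00 2.49987252e-01 1.20560580e-04 5.12345871e-02
197.370639 0.00000000e+00 2.43879583e-01 1.05872866e-04 5.23585207e-02
213.485768 0.00000000e+00 2.37744828e-01 9.37004978e-05 5.34039316e-02
230.916684 0.00000000e+00 2.31596770e-01 8.37038387e-05 5.43667464e-02
249.770817 0.00000000e+00 2.25448632e-01 7.55845941e-05 5.52435442e-02
270.164373 0.00000000e+00 2.19312924e-01 6.90773235e-05 5.60315325e-02
292.223044 0.00000000e+00 2.13201316e-01 6.39427961e-05 5.67285074e-02
316.082785 0.00000000e+00 2.07124539e-01 5.99633931e-05 5.73328044e-02
341.890651 0.00000000e+00 2.01092322e-01 5.69406305e-05 5.78432420e-02
369.805707 0.00000000e+00 1.95113363e-01 5.46947021e-05 5.82590659e-02
400.000000 0.00000000e+00 1.89195335e-01 5.30653405e-05 5.85798950e-02
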