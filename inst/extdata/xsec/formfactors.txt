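# IT92 4-Gaussian+c atomic form factor coefficients F(s), s = sin(theta/2)/lambda [1/A]
# F(s) = sum_i a_i exp(-b_i s^2) + c for s <= 2; F(s) = F(2) (2/s)^2 beyond.
# columns: element a1 a2 a3 a4 b1 b2 b3 b4 c
H 0.493002 0.322912 0.140191 0.04081 10.5109 26.1257 3.14236 57.7997 0.003038
C 2.31 1.02 1.5886 0.865 20.8439 10.2075 0.5687 51.6512 0.2156
N 12.2126 3.1322 2.0125 1.1663 0.0057 9.8933 28.9975 0.5826 -11.529
O 3.0485 2.2868 1.5463 0.867 13.2771 5.7011 0.3239 32.9089 0.2508
Si 6.2915 3.0353 1.9891 1.541 2.4386 32.3337 0.6785 81.6937 1.1407
P 6.4345 4.1791 1.78 1.4908 1.9067 27.157 0.526 68.1645 1.1149
S 6.9053 5.2034 1.4379 1.5863 1.4679 22.2151 0.2536 56.172 0.8669
Ar 7.4845 6.7723 0.6539 1.6442 0.9072 14.8407 43.8983 33.3929 1.4445
Ti 9.7595 7.3558 1.6991 1.9021 7.8508 0.5 35.6338 116.105 1.2807
Cr 10.6406 7.3537 3.324 1.4922 6.1038 0.392 20.2626 98.7399 1.1832
Mn 11.2819 7.3573 3.0193 2.2441 5.3409 0.3432 17.8674 83.7543 1.0896
Fe 11.7695 7.3573 3.5222 2.3045 4.7611 0.3072 15.3535 76.8805 1.0369
Ni 12.8376 7.292 4.4438 2.38 3.8785 0.2565 12.1763 66.3421 1.0341
Mo 3.7025 17.2356 12.8876 3.7429 0.2772 1.0958 11.004 61.6584 4.3875
Yb 28.6641 15.4345 15.3087 2.98963 1.9889 0.257119 10.6647 100.417 7.56672
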