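sample,L_before,C_before,L_binomial,C_binomial,L_median,C_median,L_gaussian,C_gaussian
1,33.0,0.37,57.6,1.05,57.4,1.05,57.5,1.04
2,32.3,0.48,56.8,1.40,56.6,1.27,56.7,1.35
3,30.5,0.38,57.3,1.21,57.7,1.08,56.9,1.18
4,37.15,0.39,64.1,1.13,64.3,1.12,64.2,1.09
5,43.0,0.50,59.43,1.21,60.0,1.23,59.0,1.20
6,35.39,0.62,60.7,1.69,60.5,1.58,60.3,1.66
7,33.48,0.38,60.2,1.11,60.22,1.03,60.4,1.05
8,42.57,0.42,59.7,1.22,59.6,1.10,59.6,1.13
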