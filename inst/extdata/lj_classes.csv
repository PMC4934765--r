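lj,sigma_nm,eps_kj
CT,0.339967,0.45773
C,0.339967,0.359824
N,0.325,0.71128
O,0.295992,0.87864
OH,0.306647,0.880314
OS,0.300001,0.71128
P,0.374177,0.8368
S,0.356359,1.046
H,0.106908,0.065689
HO,0.0,0.0
HS,0.106908,0.065689
HC,0.264953,0.065689
H1,0.247135,0.065689
H2,0.229317,0.065689
H3,0.211499,0.065689
HA,0.259964,0.06276
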