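index,label,charge
1,O1,-0.80
2,C2H4Cl,0.53
3,Cl1,-0.70
4,H1,0.27
5,H2,0.31
6,H3,0.09
7,CH3CO2,-0.73
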