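index,label,charge
1,O1,-0.88
2,C2H4Cl,0.33
3,Cl1,-0.34
4,H1,0.26
5,H2,0.30
6,H3,0.11
7,CH3CO2,-0.94
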