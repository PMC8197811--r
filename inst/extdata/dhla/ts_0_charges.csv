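index,label,charge
1,O1,-0.85
2,C2H4Cl,0.47
3,Cl1,-0.58
7,CH3CO2,-0.89
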