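index,label,charge
1,O1,-0.55
2,C2H4Cl,0.42
3,Cl1,-0.46
7,CH3CO2,-0.62
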