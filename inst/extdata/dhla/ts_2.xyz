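7
synthetic placeholder geometry; d(O1-C1)=2.00 A, d(C1-Cl1)=2.30 A
O        0.000000       0.000000       0.000000
C        0.000000       0.000000       2.000000
Cl       0.000000       0.000000       4.300000
H        3.000000       0.000000       0.000000
H        3.000000       1.000000       0.000000
H        3.000000       2.000000       0.000000
X        3.000000       3.000000       0.000000
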