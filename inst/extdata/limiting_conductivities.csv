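name,z,lambda0
H,1,349.65
Li,1,38.66
Na,1,50.08
K,1,73.48
Cs,1,77.2
NH4,1,73.5
NMDG,1,25.0
TEA,1,32.66
Mg,2,53.0
Ca,2,59.47
Ba,2,63.6
Cl,-1,76.31
Br,-1,78.1
F,-1,55.4
I,-1,76.8
NO3,-1,71.42
OH,-1,198.0
HCO3,-1,44.5
methanesulfonate,-1,48.8
gluconate,-1,24.4
isethionate,-1,52.4
acetate,-1,40.9
SO4,-2,80.0
HPO4,-2,57.0
H2PO4,-1,36.0
HEPES,-1,22.05
MES,-1,26.8
EGTA,-2,24.0
glutamate,-1,26.0
aspartate,-1,30.6
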