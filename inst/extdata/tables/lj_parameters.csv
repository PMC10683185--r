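label,epsilon,sigma,origin,note
C,0.080,3.500,reference,
N_NT,0.203,3.215,reference,
B_NT,0.453,3.380,reference,
S,0.250,3.550,reference,
N,0.170,3.250,reference,
H,0.018,0.094,reference,sigma as printed in the source table; suspiciously small - override via forcefield() if desired
H_C,0.050,2.500,reference,H bonded to aromatic or aliphatic C
O_W,0.1521,3.1507,water_model,three-site water oxygen
H_W,0.000,0.000,water_model,three-site water hydrogen (no LJ site)
O,0.1521,3.1507,fallback,solute oxygen; no published row - water-O parameters adopted
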