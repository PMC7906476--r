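name	smarts
aromatic_ring	c1ccccc1
nitro	[N+](=O)[O-]
nitroso	[NX2]=O
aromatic_amine	c[NX3;H2,H1]
aldehyde	[CX3H1](=O)[#6]
epoxide	C1OC1
michael_acceptor	C=CC=O
azo	N=N
thiol	[SX2H]
alkyl_halide	[CX4][Cl,Br,I]
hydrazine	[NX3][NX3]
anhydride	C(=O)OC(=O)
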