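name	smiles
ethanol	CCO
aspirin	CC(=O)Oc1ccccc1C(=O)O
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
paracetamol	CC(=O)Nc1ccc(O)cc1
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
benzene	c1ccccc1
toluene	Cc1ccccc1
phenol	Oc1ccccc1
aniline	Nc1ccccc1
pyridine	c1ccncc1
imidazole	c1cnc[nH]1
furan	c1ccoc1
thiophene	c1ccsc1
cyclohexane	C1CCCCC1
acetone	CC(=O)C
acetic_acid	CC(=O)O
glycine	NCC(=O)O
alanine	CC(N)C(=O)O
urea	NC(=O)N
glycerol	OCC(O)CO
lactic_acid	CC(O)C(=O)O
pyruvic_acid	CC(=O)C(=O)O
succinic_acid	OC(=O)CCC(=O)O
citrate_core	OC(=O)CC(O)(CC(=O)O)C(=O)O
nicotinamide	NC(=O)c1cccnc1
benzamide	NC(=O)c1ccccc1
benzoic_acid	OC(=O)c1ccccc1
salicylic_acid	OC(=O)c1ccccc1O
catechol	Oc1ccccc1O
resorcinol	Oc1cccc(O)c1
styrene	C=Cc1ccccc1
naphthalene	c1ccc2ccccc2c1
indole	c1ccc2[nH]ccc2c1
quinoline	c1ccc2ncccc2c1
morpholine	C1COCCN1
piperidine	C1CCNCC1
piperazine	C1CNCCN1
pyrrolidine	C1CCNC1
dimethylamine	CNC
triethylamine	CCN(CC)CC
nitrobenzene	O=[N+]([O-])c1ccccc1
chlorobenzene	Clc1ccccc1
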