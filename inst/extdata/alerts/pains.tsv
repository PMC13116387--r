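# PAINS structural-alert catalog (curated subset, v1).
# Pan-assay interference substructure classes (frequent-hitter families:
# catechols, quinones, rhodanines, hydroxyphenyl hydrazones, azo dyes,
# alkylidene barbiturates, Mannich phenols, cross-conjugated enones).
# Columns: name <TAB> smarts. SMARTS written for OpenBabel matching on
# heavy-atom structures with implicit hydrogens.
catechol_A	[OX2H]c1ccccc1[OX2H]
hydroquinone_A	[OX2H]c1ccc([OX2H])cc1
quinone_A	O=C1C=CC(=O)C=C1
ortho_quinone_A	O=C1C(=O)C=CC=C1
naphthoquinone_A	O=C1C(=O)c2ccccc2C1
rhodanine_A	O=C1CSC(=S)N1
ene_rhodanine_A	[#6]=C1SC(=S)NC1=O
ene_thiazolidinone_A	[#6]=C1SC(=O)NC1=O
hydroxyphenyl_hydrazone_A	[OX2H]c1ccccc1C=N[NX3]
phenol_Schiff_A	[OX2H]c1ccccc1C=Nc2ccccc2
azo_aromatic_A	cN=Nc
alkylidene_barbiturate_A	[#6]=C1C(=O)NC(=O)NC1=O
mannich_phenol_A	[OX2H]c1ccccc1C[NX3;!$(N=O)]
dienone_A	[#6]C=CC(=O)C=C[#6]
ene_one_ene_A	C=CC(=O)C=C
anil_alkylidene_A	c[CH]=[CH]C(=O)c
imine_phenol_A	[OX2H]c1ccccc1C=[N;!R]
aminothiophene_ester_A	Nc1sccc1C(=O)O[#6]
nitrobenzofurazan_A	[O-][N+](=O)c1ccc2nonc2c1
beta_keto_phenol_A	[OX2H]c1ccccc1C(=O)[CH2]C(=O)
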