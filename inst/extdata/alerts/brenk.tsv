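# BRENK unwanted-functionality catalog (curated set, v1).
# Reactive, toxic or metabolically unstable groups flagged in lead-likeness
# filtering (acyl halides, aldehydes, Michael acceptors, nitro groups,
# hydrazines, peroxides, heavy atoms, long aliphatic chains, ...).
# Columns: name <TAB> smarts. SMARTS written for OpenBabel matching on
# heavy-atom structures with implicit hydrogens.
acyl_halide	[CX3](=O)[Cl,Br,I]
aldehyde	[CX3H1](=O)[#6]
alkyl_halide	[CX4][Br,I]
anhydride	[CX3](=O)[OX2][CX3](=O)
azide	N=[N+]=[N-]
aliphatic_azo	[CX4]N=N[CX4]
diazonium	[N+]#N
epoxide	[C;r3]1[O;r3][C;r3]1
aziridine	[C;r3]1[N;r3][C;r3]1
hydrazine	[NX3;!$(NC=O)][NX3;!$(NC=O)]
hydrazone	[CX3;!R]=[NX2][NX3]
isocyanate	[NX2]=C=[OX1]
isothiocyanate	[NX2]=C=[SX1]
michael_acceptor	[CX3]=[CX3][CX3](=O)[#6;!$([#6][OX2H])]
nitro	[N+](=O)[O-]
nitroso	[#6][NX2]=[OX1]
oxime	[CX3]=[NX2][OX2H]
peroxide	[OX2][OX2]
phosphorus	[#15]
quaternary_nitrogen	[N+X4]
thiol	[SX2H]
thiourea	[NX3][CX3](=S)[NX3]
thioester	[SX2][CX3](=[OX1])
sulfonyl_halide	S(=O)(=O)[Cl,Br]
sulfonic_acid	S(=O)(=O)[OX2H]
disulfide	[SX2][SX2]
triflate	[OX2]S(=O)(=O)C(F)(F)F
beta_lactam	[N;R]1[C;R](=O)[C;R][C;R]1
polyene_chain	C=CC=CC=CC=C
aliphatic_long_chain	[R0;CX4][R0;CX4][R0;CX4][R0;CX4][R0;CX4][R0;CX4][R0;CX4]
polyhalogenated_aromatic	c([F,Cl,Br,I])c([F,Cl,Br,I])c([F,Cl,Br,I])
heavy_metal	[#80,#48,#33,#51,#82,#50]
crown_ether_motif	[OX2]CC[OX2]CC[OX2]CC[OX2]
imine_acyclic	[CX4][CX3;!R]=[NX2;!R][CX4]
enol_ether_acyclic	[CX3;!R]=[CX3;!R][OX2][CX4]
carbazide	[NX3][CX3](=[OX1])[NX3][NX3]
charged_oxygen	[O-;!$([O-][N+])]
cyanamide	[NX3][CX2]#[NX1]
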