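# Curated SMILES panel backing the synthetic compound-library generator.
# Strata are defined by the grade each structure receives under the
# default seven-criterion scorer: approved oral drugs and drug-like
# leads populate the upper grades; borderline, alert-bearing, oversized
# or highly complex structures populate the lower grades.
# Columns: name <TAB> smiles. Structures are public-domain textbook
# molecules written from their constitution.
aspirin	CC(=O)Oc1ccccc1C(=O)O
paracetamol	CC(=O)Nc1ccc(O)cc1
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
naproxen	COc1ccc2cc(ccc2c1)C(C)C(=O)O
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
nicotinamide	NC(=O)c1cccnc1
benzamide	NC(=O)c1ccccc1
acetanilide	CC(=O)Nc1ccccc1
antipyrine	CC1=CC(=O)N(c2ccccc2)N1C
lidocaine	CCN(CC)CC(=O)Nc1c(C)cccc1C
procaine	CCN(CC)CCOC(=O)c1ccc(N)cc1
benzocaine	CCOC(=O)c1ccc(N)cc1
atenolol	CC(C)NCC(O)COc1ccc(CC(N)=O)cc1
propranolol	CC(C)NCC(O)COc1cccc2ccccc12
metoprolol	COCCc1ccc(OCC(O)CNC(C)C)cc1
diazepam	CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1
alprazolam	Cc1nnc2CN=C(c3ccccc3)c3cc(Cl)ccc3-n12
caffeine_analog	Cn1cnc2c1c(=O)[nH]c(=O)n2C
theophylline	Cn1c(=O)c2[nH]cnc2n(C)c1=O
celecoxib	Cc1ccc(cc1)-c1cc(nn1-c1ccc(cc1)S(N)(=O)=O)C(F)(F)F
sulfamethoxazole	Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1
trimethoprim	COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC
fluoxetine	CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1
imipramine	CN(C)CCCN1c2ccccc2CCc2ccccc21
chlorpromazine	CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21
haloperidol	OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1
warfarin	CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O
ketoprofen	CC(C(=O)O)c1cccc(c1)C(=O)c1ccccc1
indomethacin	COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1
olaparib	C1CC1C(=O)N2CCN(CC2)C(=O)C3=C(C=CC(=C3)CC4=NNC(=O)C5=CC=CC=C54)F
ly294002	C1COCCN1C2=CC(=O)C3=C(O2)C(=CC=C3)C4=CC=CC=C4
imatinib	Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(n1)-c1cccnc1
gefitinib	COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1
erlotinib	COCCOc1cc2ncnc(Nc3cccc(c3)C#C)c2cc1OCCOC
sildenafil	CCCc1nn(C)c2c1nc([nH]c2=O)-c1cc(ccc1OCC)S(=O)(=O)N1CCN(C)CC1
metronidazole	Cc1ncc(n1CCO)[N+](=O)[O-]
chloramphenicol	OCC(NC(=O)C(Cl)Cl)C(O)c1ccc(cc1)[N+](=O)[O-]
nitrofurantoin	O=C1CN(N=Cc2ccc(o2)[N+](=O)[O-])C(=O)N1
dopamine	NCCc1ccc(O)c(O)c1
adrenaline	CNCC(O)c1ccc(O)c(O)c1
isoprenaline	CC(C)NCC(O)c1ccc(O)c(O)c1
levodopa	NC(Cc1ccc(O)c(O)c1)C(=O)O
quercetin	Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O
catechin	Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2
curcumin	COc1cc(C=CC(=O)CC(=O)C=Cc2ccc(O)c(OC)c2)ccc1O
resveratrol	Oc1ccc(C=Cc2cc(O)cc(O)c2)cc1
rhodanine_hit	O=C1CSC(=S)N1c1ccccc1
ene_rhodanine_hit	O=C1NC(=S)SC1=Cc1ccccc1
methylene_blue	CN(C)c1ccc2nc3ccc(cc3[s+]c2c1)N(C)C
menadione	CC1=CC(=O)c2ccccc2C1=O
lawsone	Oc1cc(=O)c2ccccc2c1=O
doxorubicin_core	COc1cccc2C(=O)c3c(O)c4CC(O)(CC(O)c4c(O)c3C(=O)c12)C(=O)CO
tolcapone	Cc1ccc(cc1)C(=O)c1ccc(O)c(O)c1[N+](=O)[O-]
entacapone_like	CCN(CC)C(=O)C(=CC1=CC(=C(C(=C1)O)O)[N+](=O)[O-])C#N
hexachlorophene_half	Oc1ccc(Cl)cc1Cl
triclosan	Oc1cc(Cl)ccc1Oc1ccc(Cl)cc1Cl
octanoic_acid	CCCCCCCC(=O)O
palmitic_acid	CCCCCCCCCCCCCCCC(=O)O
oleyl_amine	CCCCCCCCC=CCCCCCCCCN
cetylpyridinium	CCCCCCCCCCCCCCCC[n+]1ccccc1
spermine	NCCCNCCCCNCCCN
decane	CCCCCCCCCC
squalene_half	CC(C)=CCCC(C)=CCCC(C)=CCCC=C(C)C
cholesterol	CC(C)CCCC(C)C1CCC2C1(CCC3C2CC=C4C3(CCC(C4)O)C)C
cholic_acid	CC(CCC(=O)O)C1CCC2C1(C)C(O)CC1C2C(O)CC2CC(O)CCC12C
estradiol	CC12CCC3c4ccc(O)cc4CCC3C1CCC2O
testosterone	CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O
dexamethasone_core	CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)CO
erythromycin_core	CCC1OC(=O)C(C)C(O)C(C)C(O)C(C)CC(C)C(=O)C(C)C(O)C1C
cyclosporin_fragment	CC(C)CC1NC(=O)C(C)NC(=O)C(C(C)C)NC(=O)C(CC(C)C)N(C)C(=O)C(C)NC1=O
vancomycin_fragment	NC(Cc1ccc(Oc2ccc(cc2)C(O)C(N)C(=O)O)cc1)C(=O)O
dextran_fragment	OCC1OC(OCC2OC(O)C(O)C(O)C2O)C(O)C(O)C1O
raffinose_like	OCC1OC(OCC2OC(OC3(CO)OC(CO)C(O)C3O)C(O)C(O)C2O)C(O)C(O)C1O
heparin_fragment	OC1C(O)C(OC(C1O)C(=O)O)OC1C(O)C(O)C(CO)OC1OS(=O)(=O)O
peptide_RGD	NC(=N)NCCCC(NC(=O)CN)C(=O)NCC(=O)NC(CC(=O)O)C(=O)O
polymyxin_fragment	CC(C)CC(N)C(=O)NC(CCN)C(=O)NC(C(C)O)C(=O)NC(CCN)C(=O)O
gadolinium_chelate	OC(=O)CN(CCN(CC(=O)O)CC(=O)O)CCN(CC(=O)O)CC(=O)O
phytic_acid_half	OP(=O)(O)OC1C(OP(=O)(O)O)C(O)C(OP(=O)(O)O)C(O)C1O
edta	OC(=O)CN(CC(=O)O)CCN(CC(=O)O)CC(=O)O
tannin_fragment	Oc1cc(cc(O)c1O)C(=O)OC1OC(COC(=O)c2cc(O)c(O)c(O)c2)C(O)C(O)C1O
polyene_dicatechol	Oc1ccc(cc1O)C=CC=CC=CC=CC(=O)C=CC=CC=Cc1ccc(O)c(O)c1
catechol_peptide	OC(=O)C(N)CC(=O)NC(CCCNC(=N)N)C(=O)NC(Cc1ccc(O)c(O)c1)C(=O)NC(CCCNC(=N)N)C(=O)NC(CC(=O)O)C(=O)NC(Cc1ccc(O)c(O)c1)C(=O)O
tetrasaccharide	OCC1OC(O)C(O)C(O)C1OC1OC(CO)C(O)C(O)C1OC1OC(CO)C(O)C(O)C1OC1OC(CO)C(O)C(O)C1O
lecithin_like	CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC(=O)OC(COC(=O)CCCCCCCCCCCCCCC)COP(=O)(O)OCC[N+](C)(C)C
digalloyl_glucoside	Oc1cc(O)c(O)cc1C(=O)OC1C(OC(=O)c2cc(O)c(O)c(O)c2)C(OC(=O)c2cc(O)c(O)c(O)c2)C(CO)OC1OC(=O)c1cc(O)c(O)c(O)c1
cyclo_catechol_peptide	CC(C)CC1NC(=O)C(CCCCN)NC(=O)C(Cc2ccc(O)c(O)c2)NC(=O)C(CCCNC(=N)N)NC(=O)C(CC(=O)O)NC(=O)C(Cc2ccc(O)c(O)c2)NC1=O
octacosanol_ene	CCCCCCCCCCCCCCCCCCCCCCCCCCCCO
heneicosanedioic_acid	OC(=O)CCCCCCCCCCCCCCCCCCCC(=O)O
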