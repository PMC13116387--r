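# Protein atom role templates for distance-cutoff interaction typing.
# Columns: resid <TAB> atom <TAB> roles (comma-separated).
# resid "*" applies to every amino-acid residue (backbone atoms).
# Roles: donor, acceptor, cation, anion, hydrophobic, ring<k> (aromatic
# ring membership; atoms sharing a ring<k> tag within one residue form
# one ring whose centroid is used for pi contacts).
*	N	donor
*	O	acceptor
*	OXT	anion,acceptor
SER	OG	donor,acceptor
THR	OG1	donor,acceptor
THR	CG2	hydrophobic
TYR	OH	donor,acceptor
TYR	CB	hydrophobic
TYR	CG	hydrophobic,ring1
TYR	CD1	hydrophobic,ring1
TYR	CD2	hydrophobic,ring1
TYR	CE1	hydrophobic,ring1
TYR	CE2	hydrophobic,ring1
TYR	CZ	ring1
CYS	SG	donor
CYS	CB	hydrophobic
ASN	OD1	acceptor
ASN	ND2	donor
ASN	CB	hydrophobic
GLN	OE1	acceptor
GLN	NE2	donor
GLN	CB	hydrophobic
GLN	CG	hydrophobic
ASP	OD1	anion,acceptor
ASP	OD2	anion,acceptor
ASP	CB	hydrophobic
GLU	OE1	anion,acceptor
GLU	OE2	anion,acceptor
GLU	CB	hydrophobic
GLU	CG	hydrophobic
LYS	NZ	cation,donor
LYS	CB	hydrophobic
LYS	CG	hydrophobic
LYS	CD	hydrophobic
ARG	NE	donor
ARG	NH1	cation,donor
ARG	NH2	cation,donor
ARG	CB	hydrophobic
ARG	CG	hydrophobic
HIS	ND1	donor,acceptor,ring1
HIS	NE2	donor,acceptor,ring1
HIS	CG	ring1
HIS	CD2	ring1
HIS	CE1	ring1
HIS	CB	hydrophobic
TRP	NE1	donor
TRP	CB	hydrophobic
TRP	CG	ring1
TRP	CD1	ring1
TRP	CD2	ring1,ring2
TRP	CE2	ring1,ring2
TRP	CE3	hydrophobic,ring2
TRP	CZ2	hydrophobic,ring2
TRP	CZ3	hydrophobic,ring2
TRP	CH2	hydrophobic,ring2
PHE	CB	hydrophobic
PHE	CG	hydrophobic,ring1
PHE	CD1	hydrophobic,ring1
PHE	CD2	hydrophobic,ring1
PHE	CE1	hydrophobic,ring1
PHE	CE2	hydrophobic,ring1
PHE	CZ	hydrophobic,ring1
ALA	CB	hydrophobic
VAL	CB	hydrophobic
VAL	CG1	hydrophobic
VAL	CG2	hydrophobic
LEU	CB	hydrophobic
LEU	CG	hydrophobic
LEU	CD1	hydrophobic
LEU	CD2	hydrophobic
ILE	CB	hydrophobic
ILE	CG1	hydrophobic
ILE	CG2	hydrophobic
ILE	CD1	hydrophobic
MET	CB	hydrophobic
MET	CG	hydrophobic
MET	CE	hydrophobic
PRO	CB	hydrophobic
PRO	CG	hydrophobic
PRO	CD	hydrophobic
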