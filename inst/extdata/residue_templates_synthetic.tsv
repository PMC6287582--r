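# Synthetic residue-template table: CHARMM-style per-atom types and partial
# charges (elementary charge units) for the 20 standard amino acids and the
# three histidine protonation variants. Written from standard values for use
# when no PSF topology is supplied; per-residue charges sum to the formal
# charge (0 for neutral, -1 ASP/GLU, +1 LYS/ARG/HSP).
# columns: resname atom type charge
resname	atom	type	charge
BB	N	NH1	-0.47
BB	HN	H	0.31
BB	CA	CT1	0.07
BB	HA	HB	0.09
BB	C	C	0.51
BB	O	O	-0.51
GLY	N	NH1	-0.47
GLY	HN	H	0.31
GLY	CA	CT2	-0.02
GLY	HA1	HB	0.09
GLY	HA2	HB	0.09
GLY	C	C	0.51
GLY	O	O	-0.51
PRO	N	N	-0.29
PRO	CA	CT1	0.02
PRO	HA	HB	0.09
PRO	CB	CT2	-0.18
PRO	HB1	HA	0.09
PRO	HB2	HA	0.09
PRO	CG	CT2	-0.18
PRO	HG1	HA	0.09
PRO	HG2	HA	0.09
PRO	CD	CT2	0.00
PRO	HD1	HA	0.09
PRO	HD2	HA	0.09
PRO	C	C	0.51
PRO	O	O	-0.51
ALA	CB	CT3	-0.27
ALA	HB1	HA	0.09
ALA	HB2	HA	0.09
ALA	HB3	HA	0.09
VAL	CB	CT1	-0.09
VAL	HB	HA	0.09
VAL	CG1	CT3	-0.27
VAL	HG11	HA	0.09
VAL	HG12	HA	0.09
VAL	HG13	HA	0.09
VAL	CG2	CT3	-0.27
VAL	HG21	HA	0.09
VAL	HG22	HA	0.09
VAL	HG23	HA	0.09
LEU	CB	CT2	-0.18
LEU	HB1	HA	0.09
LEU	HB2	HA	0.09
LEU	CG	CT1	-0.09
LEU	HG	HA	0.09
LEU	CD1	CT3	-0.27
LEU	HD11	HA	0.09
LEU	HD12	HA	0.09
LEU	HD13	HA	0.09
LEU	CD2	CT3	-0.27
LEU	HD21	HA	0.09
LEU	HD22	HA	0.09
LEU	HD23	HA	0.09
ILE	CB	CT1	-0.09
ILE	HB	HA	0.09
ILE	CG2	CT3	-0.27
ILE	HG21	HA	0.09
ILE	HG22	HA	0.09
ILE	HG23	HA	0.09
ILE	CG1	CT2	-0.18
ILE	HG11	HA	0.09
ILE	HG12	HA	0.09
ILE	CD	CT3	-0.27
ILE	HD1	HA	0.09
ILE	HD2	HA	0.09
ILE	HD3	HA	0.09
SER	CB	CT2	0.05
SER	HB1	HA	0.09
SER	HB2	HA	0.09
SER	OG	OH1	-0.66
SER	HG1	H	0.43
THR	CB	CT1	0.14
THR	HB	HA	0.09
THR	OG1	OH1	-0.66
THR	HG1	H	0.43
THR	CG2	CT3	-0.27
THR	HG21	HA	0.09
THR	HG22	HA	0.09
THR	HG23	HA	0.09
CYS	CB	CT2	-0.11
CYS	HB1	HA	0.09
CYS	HB2	HA	0.09
CYS	SG	S	-0.23
CYS	HG1	HS	0.16
MET	CB	CT2	-0.18
MET	HB1	HA	0.09
MET	HB2	HA	0.09
MET	CG	CT2	-0.14
MET	HG1	HA	0.09
MET	HG2	HA	0.09
MET	SD	S	-0.09
MET	CE	CT3	-0.22
MET	HE1	HA	0.09
MET	HE2	HA	0.09
MET	HE3	HA	0.09
PHE	CB	CT2	-0.18
PHE	HB1	HA	0.09
PHE	HB2	HA	0.09
PHE	CG	CA	0.00
PHE	CD1	CA	-0.115
PHE	HD1	HP	0.115
PHE	CD2	CA	-0.115
PHE	HD2	HP	0.115
PHE	CE1	CA	-0.115
PHE	HE1	HP	0.115
PHE	CE2	CA	-0.115
PHE	HE2	HP	0.115
PHE	CZ	CA	-0.115
PHE	HZ	HP	0.115
TYR	CB	CT2	-0.18
TYR	HB1	HA	0.09
TYR	HB2	HA	0.09
TYR	CG	CA	0.00
TYR	CD1	CA	-0.115
TYR	HD1	HP	0.115
TYR	CD2	CA	-0.115
TYR	HD2	HP	0.115
TYR	CE1	CA	-0.115
TYR	HE1	HP	0.115
TYR	CE2	CA	-0.115
TYR	HE2	HP	0.115
TYR	CZ	CA	0.11
TYR	OH	OH1	-0.54
TYR	HH	H	0.43
TRP	CB	CT2	-0.18
TRP	HB1	HA	0.09
TRP	HB2	HA	0.09
TRP	CG	CY	-0.03
TRP	CD1	CA	0.035
TRP	HD1	HP	0.115
TRP	NE1	NY	-0.61
TRP	HE1	H	0.38
TRP	CE2	CPT	0.13
TRP	CD2	CPT	-0.02
TRP	CE3	CA	-0.115
TRP	HE3	HP	0.115
TRP	CZ3	CA	-0.115
TRP	HZ3	HP	0.115
TRP	CZ2	CA	-0.115
TRP	HZ2	HP	0.115
TRP	CH2	CA	-0.115
TRP	HH2	HP	0.115
ASP	CB	CT2	-0.28
ASP	HB1	HA	0.09
ASP	HB2	HA	0.09
ASP	CG	CC	0.62
ASP	OD1	OC	-0.76
ASP	OD2	OC	-0.76
GLU	CB	CT2	-0.18
GLU	HB1	HA	0.09
GLU	HB2	HA	0.09
GLU	CG	CT2	-0.28
GLU	HG1	HA	0.09
GLU	HG2	HA	0.09
GLU	CD	CC	0.62
GLU	OE1	OC	-0.76
GLU	OE2	OC	-0.76
ASN	CB	CT2	-0.18
ASN	HB1	HA	0.09
ASN	HB2	HA	0.09
ASN	CG	CC	0.55
ASN	OD1	O	-0.55
ASN	ND2	NH2	-0.62
ASN	HD21	H	0.32
ASN	HD22	H	0.30
GLN	CB	CT2	-0.18
GLN	HB1	HA	0.09
GLN	HB2	HA	0.09
GLN	CG	CT2	-0.18
GLN	HG1	HA	0.09
GLN	HG2	HA	0.09
GLN	CD	CC	0.55
GLN	OE1	O	-0.55
GLN	NE2	NH2	-0.62
GLN	HE21	H	0.32
GLN	HE22	H	0.30
LYS	CB	CT2	-0.18
LYS	HB1	HA	0.09
LYS	HB2	HA	0.09
LYS	CG	CT2	-0.18
LYS	HG1	HA	0.09
LYS	HG2	HA	0.09
LYS	CD	CT2	-0.18
LYS	HD1	HA	0.09
LYS	HD2	HA	0.09
LYS	CE	CT2	0.21
LYS	HE1	HA	0.05
LYS	HE2	HA	0.05
LYS	NZ	NH3	-0.30
LYS	HZ1	HC	0.33
LYS	HZ2	HC	0.33
LYS	HZ3	HC	0.33
ARG	CB	CT2	-0.18
ARG	HB1	HA	0.09
ARG	HB2	HA	0.09
ARG	CG	CT2	-0.18
ARG	HG1	HA	0.09
ARG	HG2	HA	0.09
ARG	CD	CT2	0.20
ARG	HD1	HA	0.09
ARG	HD2	HA	0.09
ARG	NE	NC2	-0.70
ARG	HE	HC	0.44
ARG	CZ	C	0.64
ARG	NH1	NC2	-0.80
ARG	HH11	HC	0.46
ARG	HH12	HC	0.46
ARG	NH2	NC2	-0.80
ARG	HH21	HC	0.46
ARG	HH22	HC	0.46
HSD	CB	CT2	-0.09
HSD	HB1	HA	0.09
HSD	HB2	HA	0.09
HSD	ND1	NR1	-0.36
HSD	HD1	H	0.32
HSD	CG	CPH1	-0.05
HSD	CE1	CPH2	0.25
HSD	HE1	HR1	0.13
HSD	NE2	NR2	-0.70
HSD	CD2	CPH1	0.22
HSD	HD2	HR3	0.10
HSE	CB	CT2	-0.08
HSE	HB1	HA	0.09
HSE	HB2	HA	0.09
HSE	ND1	NR2	-0.70
HSE	CG	CPH1	0.22
HSE	CE1	CPH2	0.25
HSE	HE1	HR1	0.13
HSE	NE2	NR1	-0.36
HSE	HE2	H	0.32
HSE	CD2	CPH1	-0.05
HSE	HD2	HR3	0.09
HSP	CB	CT2	-0.05
HSP	HB1	HA	0.09
HSP	HB2	HA	0.09
HSP	CG	CPH1	0.19
HSP	ND1	NR3	-0.51
HSP	HD1	H	0.44
HSP	CE1	CPH2	0.32
HSP	HE1	HR2	0.18
HSP	NE2	NR3	-0.51
HSP	HE2	H	0.44
HSP	CD2	CPH1	0.19
HSP	HD2	HR1	0.13
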