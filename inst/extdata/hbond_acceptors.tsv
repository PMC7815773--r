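# Hydrogen-bond acceptor heavy atoms. res "*" = backbone carbonyl O.
res	atom
*	O
ASP	OD1
ASP	OD2
GLU	OE1
GLU	OE2
ASN	OD1
GLN	OE1
SER	OG
THR	OG1
TYR	OH
HIS	ND1
HIS	NE2
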