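# Hydrogen-bond donor heavy atoms. res "*" = backbone donor of any residue.
res	atom
*	N
ARG	NE
ARG	NH1
ARG	NH2
LYS	NZ
HIS	ND1
HIS	NE2
TRP	NE1
ASN	ND2
GLN	NE2
SER	OG
THR	OG1
TYR	OH
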