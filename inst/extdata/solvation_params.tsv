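# Atomic solvation parameters sigma (kcal/mol/A^2), Eisenberg-McLachlan style.
# Binding free energy surrogate: dG = -sum_atoms sigma(class) * dASA(atom);
# positive carbon sigma means hydrophobic burial is stabilizing (dG < 0).
class	sigma
C	0.016
S	0.021
N	-0.006
O	-0.006
chargedO	-0.024
chargedN	-0.050
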