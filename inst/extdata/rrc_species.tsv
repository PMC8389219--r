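# Radical-radical coupling of the ferulic acid phenoxyl radical with the
# hydroxyl radical: one spin-crossing (MECP) bottleneck per ring site.
# Energies relative to the separated doublet reactants; the MECP imaginary
# frequency is the singlet-state value and is written with the program's
# negative-sign convention.
name	role	G	G_unit	nu_imag_cm1	multiplicity
FAPR	reactant	0	kcal/mol		2
OH-radical	reactant	0	kcal/mol		2
MECP-C1	mecp	14.1	kcal/mol	-256	1
adduct-C1	product	-41.5	kcal/mol		1
MECP-C3	mecp	11.1	kcal/mol	-254	1
adduct-C3	product	-48.2	kcal/mol		1
MECP-C5	mecp	12.9	kcal/mol	-363	1
adduct-C5	product	-47.6	kcal/mol		1
MECP-C8	mecp	8.6	kcal/mol	-306	1
adduct-C8	product	-50.4	kcal/mol		1
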