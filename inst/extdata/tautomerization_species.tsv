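# Keto-enol tautomerization of the C5 hydroxyl adduct relayed through n
# bridging water molecules (n = 0..3). Energies relative to the keto form
# (plus its n waters); unimolecular proton transfer.
name	role	G	G_unit	nu_imag_cm1	multiplicity
keto-0w	reactant	0	kcal/mol		1
TS-0w	transition_state	72.9	kcal/mol	-1551	1
enol-0w	product	-28.2	kcal/mol		1
keto-1w	reactant	0	kcal/mol		1
TS-1w	transition_state	23.9	kcal/mol	-1384	1
enol-1w	product	-24.3	kcal/mol		1
keto-2w	reactant	0	kcal/mol		1
TS-2w	transition_state	11.8	kcal/mol	-966	1
enol-2w	product	-27.1	kcal/mol		1
keto-3w	reactant	0	kcal/mol		1
TS-3w	transition_state	10.1	kcal/mol	-838	1
enol-3w	product	-27.2	kcal/mol		1
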