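# Docking energy decompositions for ferulic acid (FA) and 5-hydroxyferulic
# acid (5OHFA) in the lipoxygenase active site. All energies kcal/mol,
# inhibition constants in micromolar.
complex_label	dG_bind	Ki_uM	dG_inter	dG_vdw_hbond_desolv	dG_elec	dG_total	dG_tor	dG_unb
LOX-FA	-8.29	0.84	-9.78	-3.37	-6.41	-0.25	1.49	-0.25
LOX-5OHFA	-7.25	4.82	-9.04	-3.75	-5.30	-1.72	1.79	-1.72
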