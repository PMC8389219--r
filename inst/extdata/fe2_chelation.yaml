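# Complexation of the hydrated ferrous ion by the ferulate (FA) and
# 5-hydroxyferulate (5OHFA) mono- and dianions, 1:1 and 1:2 metal:ligand
# stoichiometries, carboxylate coordination, quintet iron. The component free
# energies behind these reactions are not part of the digest tables, so each
# reaction carries its reported Delta_r G (kcal/mol, aqueous, 298.15 K, 1 M)
# as an override.
standard_state: aqueous-298.15K-1M
reactions:
  - label: Fe-FA-mono-1to1
    reactants: {"FA-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[FAFe(H2O)5]+": 1, "H2O": 1}
    delta_g_override: -9.2476
    metadata: {ratio: "1:1", ligand_state: monoanion, ligand: FA, site: carboxylate}
  - label: Fe-FA-di-1to1
    reactants: {"FA2-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[FAFe(H2O)5]": 1, "H2O": 1}
    delta_g_override: -12.3638
    metadata: {ratio: "1:1", ligand_state: dianion, ligand: FA, site: carboxylate}
  - label: Fe-FA-mono-1to1-guaiacyl
    reactants: {"FA-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[FAFe(H2O)5]+g": 1, "H2O": 1}
    delta_g_override: -2.5853
    metadata: {ratio: "1:1", ligand_state: monoanion, ligand: FA, site: guaiacyl}
  - label: Fe-FA-di-1to1-guaiacyl
    reactants: {"FA2-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[FAFe(H2O)5]g": 1, "H2O": 1}
    delta_g_override: -16.4640
    metadata: {ratio: "1:1", ligand_state: dianion, ligand: FA, site: guaiacyl}
  - label: Fe-5OHFA-mono-1to1
    reactants: {"5OHFA-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[5OHFAFe(H2O)5]+": 1, "H2O": 1}
    delta_g_override: -9.8757
    metadata: {ratio: "1:1", ligand_state: monoanion, ligand: 5OHFA, site: carboxylate}
  - label: Fe-5OHFA-di-1to1
    reactants: {"5OHFA2-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[5OHFAFe(H2O)5]": 1, "H2O": 1}
    delta_g_override: -11.2186
    metadata: {ratio: "1:1", ligand_state: dianion, ligand: 5OHFA, site: carboxylate}
  - label: Fe-5OHFA-di-1to1-catechol
    reactants: {"5OHFA2-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[5OHFAFe(H2O)5]c": 1, "H2O": 1}
    delta_g_override: -16.2287
    metadata: {ratio: "1:1", ligand_state: dianion, ligand: 5OHFA, site: catechol}
  - label: Fe-5OHFA-mono-1to1-catechol
    reactants: {"5OHFA-": 1, "[Fe(H2O)6]2+": 1}
    products: {"[5OHFAFe(H2O)5]+c": 1, "H2O": 1}
    delta_g_override: -1.8091
    metadata: {ratio: "1:1", ligand_state: monoanion, ligand: 5OHFA, site: catechol}
  - label: Fe-FA-mono-1to2
    reactants: {"FA-": 2, "[Fe(H2O)6]2+": 1}
    products: {"[(FA)2Fe(H2O)4]": 1, "H2O": 2}
    delta_g_override: -20.9369
    metadata: {ratio: "1:2", ligand_state: monoanion, ligand: FA, site: carboxylate}
  - label: Fe-FA-di-1to2
    reactants: {"FA2-": 2, "[Fe(H2O)6]2+": 1}
    products: {"[(FA)2Fe(H2O)4]2-": 1, "H2O": 2}
    delta_g_override: -23.9257
    metadata: {ratio: "1:2", ligand_state: dianion, ligand: FA, site: carboxylate}
  - label: Fe-5OHFA-mono-1to2
    reactants: {"5OHFA-": 2, "[Fe(H2O)6]2+": 1}
    products: {"[(5OHFA)2Fe(H2O)4]": 1, "H2O": 2}
    delta_g_override: -21.7620
    metadata: {ratio: "1:2", ligand_state: monoanion, ligand: 5OHFA, site: carboxylate}
  - label: Fe-5OHFA-di-1to2
    reactants: {"5OHFA2-": 2, "[Fe(H2O)6]2+": 1}
    products: {"[(5OHFA)2Fe(H2O)4]2-": 1, "H2O": 2}
    delta_g_override: -25.6670
    metadata: {ratio: "1:2", ligand_state: dianion, ligand: 5OHFA, site: carboxylate}
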