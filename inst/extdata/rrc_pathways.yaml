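# Competing radical-radical coupling pathways (one per ring site). The
# tunneling coefficients are the study's reported Eckart values, supplied as
# fixed inputs because the ZPE-corrected barrier heights behind them are not
# part of the digest tables.
pathways:
  - id: C1
    mechanism: RRC
    molecularity: bimolecular
    sigma: 1
    kappa: 1.1
    species:
      reactant: [FAPR, OH-radical]
      transition_state: MECP-C1
      product: adduct-C1
  - id: C3
    mechanism: RRC
    molecularity: bimolecular
    sigma: 1
    kappa: 1.1
    species:
      reactant: [FAPR, OH-radical]
      transition_state: MECP-C3
      product: adduct-C3
  - id: C5
    mechanism: RRC
    molecularity: bimolecular
    sigma: 1
    kappa: 1.1
    species:
      reactant: [FAPR, OH-radical]
      transition_state: MECP-C5
      product: adduct-C5
  - id: C8
    mechanism: RRC
    molecularity: bimolecular
    sigma: 1
    kappa: 0.9
    species:
      reactant: [FAPR, OH-radical]
      transition_state: MECP-C8
      product: adduct-C8
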