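# Water-assisted tautomerization series; the reported Eckart tunneling
# coefficients are supplied as fixed inputs (see rrc_pathways.yaml).
pathways:
  - id: n0
    mechanism: tautomerization
    molecularity: unimolecular
    n_waters: 0
    kappa: 1282.7
    species: {reactant: keto-0w, transition_state: TS-0w, product: enol-0w}
  - id: n1
    mechanism: tautomerization
    molecularity: unimolecular
    n_waters: 1
    kappa: 10.5
    species: {reactant: keto-1w, transition_state: TS-1w, product: enol-1w}
  - id: n2
    mechanism: tautomerization
    molecularity: unimolecular
    n_waters: 2
    kappa: 2.8
    species: {reactant: keto-2w, transition_state: TS-2w, product: enol-2w}
  - id: n3
    mechanism: tautomerization
    molecularity: unimolecular
    n_waters: 3
    kappa: 2.1
    species: {reactant: keto-3w, transition_state: TS-3w, product: enol-3w}
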