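Published reference tables for chiglitazar bound to the PPAR
ligand-binding domains, used as worked-example fixtures:

- `ppar_mmgbsa_summary.tsv` - per-system MM-GBSA binding-energy summary
  (mean and SD in kcal/mol) for the chiglitazar-PPARalpha/beta/gamma
  complexes, with grouped van der Waals, lipophilic and GB+electrostatic
  components.
- `ppar_{alpha,beta,gamma}_decomposition.tsv` - published per-residue
  MM-GBSA contributions (kcal/mol, favourable = negative) of the key
  interacting residues of each complex.
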