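# Demo analysis: 21 synthetic host species in two regions, flea and mite
# networks, with moderate null/permutation ensembles for a desk-scale run.
n_null: 200
nperm: 999
min_per_sex: 20
percentile: 95
response_scale: zscore
seed: 2025
simulate:
  n_species: 21
  hosts_per_sex: 30
  n_parasites: 15
  nb_mean: 5.0
  nb_dispersion: 1.0
  male_abundance_mult: 1.0
  male_composition_shift: 0.0
  parasite_prevalence_decay: 0.7
  abundance_mult_range: [1.0, 2.5]
  composition_shift_range: [0.0, 0.3]
  regions: [Siberia, Slovakia]
  groups: [flea, mite]
  seed: 2025
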