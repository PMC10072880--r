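# Example simulation configuration.
# class_rates are given in SNV class order:
#   G>A/C>T, T>C/A>G, G>T/C>A, G>C/C>G, T>A/A>T, T>G/A>C
reference:
  length: 16299
  gc_fraction: 0.37
  seed: 1
depth: 10000
n_molecules: 10000
seed: 20230217
profiles:
  kidney_like:
    class_rates: [2.7e-6, 8.6e-7, 4.1e-7, 1.8e-7, 2.7e-7, 9.0e-8]
    indel_rate: 4.5e-7
    clonal_fraction: 0.104
    cr_enrichment: 5
    damage_rate: 0.0
  heart_like:
    class_rates: [6.4e-7, 2.4e-7, 3.2e-7, 1.5e-7, 2.8e-8, 1.4e-8]
    indel_rate: 1.4e-7
    clonal_fraction: 0.02
    cr_enrichment: 5
    damage_rate: 0.0
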