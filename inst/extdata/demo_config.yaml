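# Demo run: a small synthetic phage universe with planted enrichment.
# Any omitted setting falls back to the package default (see read_run_config).
seed: 101
population:
  n_phages: 600
  frac_spore_host: 0.3
  n_enriched: 8
  n_null: 30
  p_spore: 0.25
  p_other: 0.02
  p_null: 0.05
scaffolds:
  n_per_gene: 6
  n_genes: 20
alignment:
  n_full_length: 57
  n_effector_only: 29
  receiver_span: [8, 130]
  effector_span: [140, 230]
  indel_rate: 0.02
enrichment:
  alpha_adj: 1.0e-6
  min_n: 30
domain:
  present_min: 0.5
  absent_max: 0.1
keep_possible_viral: true
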