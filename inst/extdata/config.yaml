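# Example pipeline configuration; absent keys keep package defaults.
maf_threshold: 0.01
flank_bp: 10
phenotype_terms:
  - retinitis pigmentosa
  - retinal dystrophy
  - usher
max_control_carriers: 0
splice_thresholds:
  maxent:
    min_score: 2
    min_variation_pct: 15
  hsf:
    min_score: 70
    min_variation_pct: 10
  nnsplice:
    min_score: 0.4
    min_variation_pct: 10
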