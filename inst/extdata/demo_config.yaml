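# Demo run: simulated two-condition retina-like experiment on a 2 Mb
# chromosome. A progenitor-like sample carries fully methylated
# photoreceptor promoters; a photoreceptor-like sample has the same
# promoters demethylated.
seed: 11
params:
  k_classes: 4
  min_cpg_per_segment: 10
  cp_penalty: 0.1
  smooth_window: 3
  fdr_target: 0.05
  n_perm: 10
  umr_lmr_cpg_threshold: 30
  region_size_filter_bp: 500
  promoter_upstream: 1000
  promoter_downstream: 200
  min_cov: 5
  overlap_rule: majority
  pmd_enabled: false
design:
  chrom_lengths:
    chr1: 2000000
  bg_spacing: 100
  island_spacing: 10
  coverage_lambda: 20
  rho: 0.05
  n_photoreceptor_genes: 12
  other_sets:
    non_photoreceptor: 40
  n_extra_umr: 10
  n_extra_lmr: 20
  n_pmd: 0
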