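{
  "synthetic": {
    "n_loci": 100,
    "locus_length": 2000,
    "gc_fraction": 0.42,
    "snp_rate": 0.006666667,
    "indel_rate": 0.001333333,
    "indel_max_len": 8,
    "disruption_prob": 0.5,
    "depth_mean": 100,
    "dispersion": 10,
    "n_replicates": 2,
    "seed": 1
  },
  "catalog": {
    "mappability_halfwidth": 60,
    "central_width": 150,
    "dedup_distance": 1000,
    "quintile_floor": 0.2,
    "imprint_margin": 100000,
    "proximal_threshold": 1000
  },
  "skew": {
    "fdr_threshold": 0.1,
    "fold_thresholds": [2, 4],
    "tf_halfwidth": 250,
    "histone_halfwidth": 500,
    "pseudocount": 1,
    "test": "beta_binomial"
  },
  "seed": 1,
  "out_dir": "hybridcre_demo_out"
}
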