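{
  "_comment": "Run configuration template. Either 'synthetic' (synthetic_spec overrides) or 'inputs' (file paths) must be set; every other key falls back to the package default shown here.",
  "synthetic": null,
  "inputs": {
    "counts": "counts.tsv",
    "taxonomy": "taxonomy.tsv",
    "metadata": "metadata.tsv",
    "tree": "tree.nwk",
    "truth": null,
    "orientation": "taxa_rows"
  },
  "filter_threshold": 1e-05,
  "rarefaction_depth": null,
  "css_quantile": 0.5,
  "beta_metric": "braycurtis",
  "n_permutations": 999,
  "envfit_axes": 2,
  "screen_variables": ["depth_m", "temperature", "air_humidity", "pH", "TOC", "TN", "moisture"],
  "indval": {"stat_threshold": 0.6, "p_threshold": 0.05},
  "enrichment": {"focus": "air", "n_perm": 2000, "alpha": 0.05},
  "network": {
    "rho_min": 0.6,
    "p_max": 0.01,
    "abundance_threshold": 5e-04,
    "fdr": true,
    "absolute": false,
    "scopes": ["overall", "air", "water", "rock", "sediment"]
  },
  "keystone_k": 3,
  "seed": 1,
  "out_dir": "results"
}
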