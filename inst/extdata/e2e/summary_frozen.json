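{
  "tool": "nucyto",
  "version": "0.1.0",
  "seed": 42,
  "config_hash": "286e9bdc",
  "n_input_rows": 257,
  "n_genes": 250,
  "tested_genes": 217,
  "n_filtered": 33,
  "n_nuclear": 22,
  "n_cytoplasmic": 5,
  "top_enrichment_term": "membrane_trafficking_like"
}
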