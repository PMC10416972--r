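# nucyto

Nucleocytoplasmic mRNA localization analysis from subcellular-fractionation
RNA-seq.

Expanded G4C2 hexanucleotide repeats in *C9orf72* — the most common genetic
cause of ALS/FTD — perturb nucleocytoplasmic transport, and one measurable
consequence is that many mRNAs become retained in the nucleus. A standard way
to quantify this is to fractionate cells into nuclear and cytoplasmic
compartments, sequence both fractions in control and repeat-expressing cells,
and compare each gene's cytosol/nucleus expression ratio between conditions.
`nucyto` implements that analysis as a tested, reusable pipeline for anyone
working with fractionated expression matrices: molecular neuroscientists
validating retention phenotypes, and bioinformaticians who need the statistic
without reassembling it from spreadsheets.

## The statistic

For gene *g*, replicate *r* and condition *c* (control or repeat), with FPKM
values from the cytoplasmic (C) and nuclear (N) fractions:

- **Filter**: keep *g* iff log2(FPKM) > −1.0 (strict) in *every* sample —
  both fractions, both conditions, all replicates — so all ratios are
  well-defined.
- **Localization ratio**: ratio_{g,c,r} = C_{g,c,r} / N_{g,c,r}, then the
  per-condition mean over replicates, CN_{g,c} = mean_r ratio_{g,c,r}.
- **Fold change**: FC_g = CN_{g,repeat} / CN_{g,control}; FC < 1 means the
  transcript moved toward the nucleus in repeat-expressing cells.
- **Test**: unpaired two-sided Student's t-test (pooled variance) on the
  per-replicate ratios, log2-transformed by default; a gene is
  `nuclear_accumulated` iff p < 0.05 and FC < 1, `cytoplasmic_accumulated`
  iff p < 0.05 and FC > 1.
- **Enrichment**: the nuclear-retained list is tested against GMT gene sets
  with an exact upper-tail hypergeometric test, P(X ≥ k),
  X ~ Hypergeom(N, K, n), over the *tested* background, with
  Benjamini–Hochberg adjustment.
- **qPCR validation**: 2^−ΔCt relative expression against fraction-specific
  housekeeping genes (nuclear Malat1, cytoplasmic GAPDH), per-condition C/N
  ratio, and fold change with the control condition normalized to 1.

A synthetic-data generator with known ground truth (planted log2 C/N shifts,
multi-locus genes, sub-threshold genes) makes every stage testable without
any download.

## Worked example

```r
library(nucyto)

cfg <- simulation_config(n_genes = 1000, seed = 7)   # 5% nuclear-shifted, 0.2% cytoplasmic
ds  <- simulate_dataset(cfg)
mat <- aggregate_by_gene(ds$matrix, ds$locus_map)    # locus-level -> gene-level
res <- localize(mat, ds$samples)
table(res$class)
#> cytoplasmic_accumulated                filtered     nuclear_accumulated
#>                      21                     151                      69
#>               unchanged
#>                     759
```

151 genes fail the expression filter (the generator plants ~10% sub-threshold
genes, plus low-abundance draws), 69 are called nuclear-accumulated (46 of
the 50 planted −1.5 log2 shifts — 3 were filtered, 1 missed — plus 23 of the
~2.5% per-direction false positives expected at raw p < 0.05), 21
cytoplasmic. The
top of the table, sorted by p-value:

```r
head(res[order(res$p_value), c("gene", "fc", "log2fc", "p_value", "class")], 3)
#>                gene        fc   log2fc      p_value               class
#> gene00249 gene00249 0.4678995 -1.095730 6.397083e-05 nuclear_accumulated
#> gene00415 gene00415 0.3753575 -1.413663 7.221512e-05 nuclear_accumulated
#> gene00287 gene00287 0.3472183 -1.526085 7.660452e-05 nuclear_accumulated
```

Over-representation of the nuclear-retained list against a simulated GMT
collection (one planted "membrane-trafficking-like" set, 20 decoys), with the
tested genes as background:

```r
tested <- subset(res, class != "filtered")
nuc <- tested$gene[tested$class == "nuclear_accumulated"]
coll <- simulate_genesets(ds$truth, seed = 7)
enrich(nuc, coll, top_k = 3, universe = tested$gene)
#>                    set_name overlap_k set_size_K query_size_n universe_size_N      p_value   adjusted_p enrichment_score
#> 1 membrane_trafficking_like        28         43           69             849 5.635329e-23 1.183419e-21        22.249081
#> 2              decoy_set_13         6         39           69             849 8.826386e-02 6.551701e-01         1.054217
#> 3              decoy_set_03         7         49           69             849 9.359573e-02 6.551701e-01         1.028744
```

The planted set recovers 28 of its 43 tested members among the 69 query genes
(p ≈ 6e−23); no decoy approaches significance. qPCR validation of two called
genes (simulated Cq values consistent with the planted shifts):

```r
cq <- simulate_qpcr(ds$truth, nuc[1:2], cfg)
qpcr_fold_changes(cq)
#>      target cn_control cn_repeat fc_vs_control control_normalized     p_value
#> 1 gene00022  0.9909581 0.2862826     0.2888948                  1 0.001635353
#> 2 gene00029  1.2364126 0.8180636     0.6616429                  1 0.061726137
```

`fc_vs_control` < 1 confirms nuclear retention relative to control (whose
ratio is 1 by construction).

## Pipeline and CLI

`run_all(run_config(...))` chains simulate/load → aggregate → localize →
enrich → qpcr into a run directory (`results.tsv`, `volcano.tsv`,
`heatmap.tsv`, `enrich.tsv`, `qpcr_fc.tsv`, `summary.json`,
`run_config.json`); the same config + seed reproduces `summary.json`
byte-identically. The command-line entry point wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "nucyto.R", package = "nucyto"))') \
    run --config run.json
# subcommands: simulate | localize | enrich | qpcr | run
```

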