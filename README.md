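# cavebiome

Statistical analysis of habitat-resolved cave microbiome surveys, as a
tested, reusable R package.

Karst-cave bacteriome studies sample four substrate niches — **air, water,
rock, sediment** — across multiple caves, sequence 16S rRNA amplicons, and
ask: do niches carry distinct communities, which taxa indicate each niche,
which environmental factors track diversity, and how are genera organized
into co-occurrence modules with keystone taxa? `cavebiome` implements that
entire downstream workflow on an OTU count table (raw-read processing is out
of scope), together with a synthetic-community generator that plants known
structure so every stage can be validated against ground truth.

## What it computes

| Stage | Method |
|---|---|
| Filtering | OTUs with whole-table relative abundance < 1e-5 discarded |
| Normalization | rarefaction (alpha), cumulative sum scaling CSS (beta), relative/CPM, genus aggregation |
| Alpha diversity | observed OTUs, Chao1 (classic & bias-corrected), Shannon `H = -Σ p_i ln p_i`, Good's coverage `1 - F1/N` |
| Beta diversity | Bray–Curtis `1 - 2Σmin(x,y)/(Σx+Σy)`, weighted UniFrac `Σ l_b |A_b - B_b|` (raw/normalized), Sørensen partition `β_sor = β_sim + β_sne` |
| Ordination & tests | PCoA (Gower centering), one-way PERMANOVA (pseudo-F, 999 permutations), envfit-style vector fitting, Spearman screens |
| Indicators | IndVal.g `√(A·B)` with permutation p; indicator iff IndVal > 0.6 and p < 0.05 |
| Enrichment | focus-niche (air) vs rest, permutation test on log2(CPM+1), BH-FDR classes enriched/depleted/unchanged |
| Networks | genera > 0.05% mean relative abundance; edges where Spearman ρ > 0.6 and BH-adjusted p < 0.01; Louvain modules, MD/CC/APL/ND/AD, Brandes betweenness, top-3 keystones, module-niche preference |

## Worked example

Generate a small synthetic survey (4 caves × 4 niches × 3 samples, 300
taxa, 10,000 reads/sample) and run the full pipeline:

```r
library(cavebiome)
cfg <- run_config(
  synthetic = list(n_caves = 4, samples_per_cave_per_niche = 3,
                   n_taxa = 300, depth = 10000, seed = 7),
  seed = 7)
rep <- run_pipeline(cfg)

rep$permanova$niche
#> PERMANOVA (niche): pseudo-F = 3.1408, R2 = 0.1764, p = 0.001 (999 permutations)

head(rep$alpha, 4)
#>        sample_id observed_otus chao1 shannon goods_coverage
#> 1   cave01_air_1           272 285.5   4.589         0.9974
#> 2   cave01_air_2           262 267.1   4.087         0.9984
#> 3   cave01_air_3           263 289.0   4.473         0.9975
#> 4 cave01_water_1           277 290.6   4.655         0.9975

head(rep$indval[rep$indval$is_indicator, ], 4)
#>     taxon_id group     A B indval p_value is_indicator
#> 1 Genus_p001   air 0.693 1  0.833   0.001         TRUE
#> 2 Genus_p002   air 0.656 1  0.810   0.001         TRUE
#> 3 Genus_p003   air 0.783 1  0.885   0.001         TRUE
#> 4 Genus_p004   air 0.794 1  0.891   0.001         TRUE

rep$networks$overall$topology
#> network topology: 48 nodes, 127 edges | AD 5.292, CC 0.618, APL 2.319,
#>   ND 6, MD 0.707 (4 modules)

rep$networks$overall$keystones
#>   rank       node betweenness degree module
#> 1    1 Genus_p069   135.16667      6      3
#> 2    2 Genus_p037   106.16667      8      2
#> 3    3 Genus_p022    62.08333      8      3
```

Reading the output: niche explains ~18% of community variance at the
minimum attainable permutation p (0.001 with 999 permutations); the planted
air indicators are recovered with specificity A ≈ 0.7–0.8 and perfect
fidelity B = 1; and the overall genus network resolves 4 modules whose
top-betweenness node (`Genus_p069`, the planted hub) bridges two planted
correlation blocks. Because the input is synthetic, the report also carries
`rep$truth_recovery` (indicator sensitivity 1.0, module ARI 1.0, hub in
keystones, PERMANOVA p = 0.001 here).

With real data, set `inputs` instead of `synthetic` (TSV count table,
taxonomy, metadata, optional Newick tree); see
`inst/extdata/run_config_template.json` for every knob. A CLI wrapper ships
as `inst/scripts/cavebiome-pipeline` (`simulate` / `run` subcommands).

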