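---
title: "cavebiome: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cavebiome: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Habitat-resolved cave microbiome surveys collect 16S rRNA amplicon samples
from four substrate niches — air, water, rock and sediment — across several
caves, and ask a fixed battery of questions: Are communities structured by
niche? Which taxa indicate each niche? Which environmental factors
(temperature, humidity, pH, TOC, TN, moisture, distance from entrance)
track diversity or composition? How do abundant genera co-occur, which
modules do they form, and which genera are keystone connectors?

`cavebiome` implements that downstream battery on a sample × OTU count
table, and — because the real sequencing data needed to reproduce any
specific survey's headline numbers is not reproducible at desk scale — a
synthetic-community generator whose planted structure turns every stage
into a testable recovery problem.

# Analysis methods and conventions

**Filtering.** OTUs whose whole-table relative abundance (total OTU count /
total table count) is below `1e-5` are discarded, the conventional
rare-OTU filter for amplicon tables. The comparison keeps an OTU at
exactly the threshold.

**Rarefaction** (`rarefy`) draws an exact multivariate hypergeometric
subsample (without replacement) per sample. The default depth is the
minimum sample total. Samples below the depth are dropped with a warning
rather than erroring, so one shallow library does not kill a run. Each
sample's draw is seeded by a child seed keyed on the sample id, and taxa
are processed in a canonical sorted order, so draws are invariant to sample
order and commute with taxon permutation.

**CSS** (`css_normalize`): per sample, the scaling factor is the sum of
counts less than or equal to the q-th lower empirical quantile (type 1) of
that sample's *nonzero* counts; output is `counts / s_j * 1000`. The
quantile is fixed at 0.5; adaptive quantile selection as implemented in
metagenomeSeq is deliberately not reproduced — a documented simplification
that keeps the normalization a closed formula.

**Alpha diversity** is computed on rarefied counts. Shannon uses the
natural log (ecology convention). Chao1 defaults to the classic estimator
`S_obs + F1^2/(2 F2)` with the `F1(F1-1)/2` fallback when `F2 = 0`; the
bias-corrected form is a flag. Good's coverage is `1 - F1/N`.

**Beta diversity** is computed on CSS-normalized tables. Weighted UniFrac
defaults to the normalized variant (bounded in [0, 1], ordination-friendly);
the raw variant is a flag. Sørensen dissimilarity is partitioned into
turnover (`beta_sim`, Simpson dissimilarity) and nestedness (`beta_sne`)
following the standard a/b/c presence algebra; additivity
`beta_sor = beta_sim + beta_sne` is enforced to 1e-12 in tests.

**PCoA** Gower-centers `-D^2/2` and eigendecomposes. Negative eigenvalues
are reported but not corrected (no Cailliez/Lingoes); coordinates exist for
positive eigenvalues only and proportions explained are relative to the
positive-eigenvalue sum.

**PERMANOVA** is one-way: pseudo-F from within/between sums of squared
distances, p-value by label permutation with the add-one convention
`(1 + #{F_perm >= F_obs}) / (1 + n_perm)`, 999 permutations by default.
Nested or stratified designs are out of scope.

**envfit** regresses the (NA-filtered, centered) variable on the first k
ordination axes; R² is the coefficient of determination, the direction is
the unit coefficient vector, and significance is the permutation tail of
R² under variable shuffling. k defaults to 2 (the plotted plane); R² is
monotone non-decreasing in k, so k is a reporting choice, not a fit choice.

**Spearman screens** use midranks everywhere, with the two-sided
t-approximation `t = rho sqrt((n-2)/(1-rho^2))`. Variables with missing
values lose only the affected samples; fewer than 4 pairs yields NA with a
warning. A BH-adjusted column is attached by default since seven factors
are screened at once.

**IndVal** is the group-equalized single-group statistic
`sqrt(A * B)` with `A` the group share of mean abundance and `B` the
within-group occurrence fraction; each taxon is reported against its argmax
group. Niche-pair combinations are not searched — the target analysis
reports single-niche indicators. The permutation test shuffles group
labels; a taxon constant across samples has an invariant statistic, so its
p-value is exactly 1. Flagging uses IndVal > 0.6 and p < 0.05.

**Enrichment** (air vs the rest) replaces the negative-binomial machinery
of count-model packages with a defined permutation test on
`log2(CPM + 1)` group means, BH-adjusted across OTUs: the classification
contract (enriched / depleted / unchanged at the 95% confidence level, by
the sign of the log2 fold change of CPM means with pseudocount 1) is
preserved while the test itself is fully specified. 2000 permutations by
default: with B permutations the smallest attainable p is `1/(B+1)`, and
BH across T taxa needs `B + 1 > T / alpha` for a lone true positive to be
detectable — a resolution constraint worth knowing when lowering B.

**Networks.** Genus tables (OTUs summed by genus label; OTUs unassigned at
genus pool under `<lowest-assigned-rank>__unclassified`) are filtered to
genera with mean relative abundance strictly above 0.05% within the network
scope (whole dataset, or one niche's samples — the per-scope reading, which
is what lets per-niche networks have different node sets). Edges require
Spearman rho > 0.6 **and** BH-adjusted p < 0.01 across all tested pairs.
Positive correlations only by default (a co-occurrence, not a
mutual-exclusion, network); `absolute = TRUE` admits |rho| > 0.6. The
empirical-null FDR tool used in some published pipelines is not
re-implemented; BH is used uniformly. Isolated genera are dropped: node
counts refer to genera participating in edges.

**Topology.** CC is the mean of local clustering coefficients with
degree-<2 nodes contributing 0 (graph-level transitivity is also reported,
since published values are tool-dependent); APL/ND are over all connected
pairs (giant-component variants reported alongside); betweenness is
Brandes, undirected, unnormalized; modules are Louvain at resolution 1,
best modularity over 10 node-order-shuffled restarts, deterministic under
the seed. Keystones are the top-3 betweenness nodes with ties broken by
degree then label.

# The synthetic world

For sample *s* (niche *n*, cave *c*) and taxon *t*, the latent
log-abundance is

    z_t(s) = mu_t + delta * [t indicator of n] + eta * [t in a block
             preferring n] + gamma_{t,c} + sum_f beta_{t,f} (x_f(s) -
             mean x_f) + sigma_u * u_t(s)

with relative abundances `softmax(z(s))` and counts
`multinomial(depth, softmax(z))`. The residual *u* carries the planted
correlation structure: members of block *b* load `sqrt(rho_b)` on a shared
factor; the hub taxon *is* a latent factor *g*, and the factors of the
`hub_links` hub-linked blocks are coupled to *g* with weight
`sqrt(hub_coupling)`. The softmax/log-normal construction (rather than
Dirichlet-multinomial) is what makes the co-occurrence ground truth
directly controllable in latent space.

Defaults and why:

| Parameter | Default | Rationale |
|---|---|---|
| caves × niches × reps | 8 × 4 × 4 = 128 samples | the emulated survey design (balanced; real surveys had 4–6 sites/cave) |
| `n_taxa` | 600 | enough for realistic rank-abundance structure at desk scale |
| `depth` | 30,000 reads | order of real per-sample depths (tens of thousands) |
| `mu_sd` | 1.5 | log-normal baseline gives few dominant phyla, long tail |
| `indicator_effect` | 2.0 (log scale) | ~7.4× niche enrichment; 5 indicators/niche |
| `n_blocks`, `block_size`, `block_rho` | 4, 12, 0.7 | the planted module structure |
| `block_niche_effect` | 0.5 | blocks *prefer* a niche (cyclically assigned) without becoming near-exclusive indicator-grade taxa |
| `hub_coupling` | 0.7 | hub–member latent correlation `sqrt(0.7 × 0.7) = 0.7` clears the 0.6 edge threshold while cross-block member correlation `0.7 × 0.7 = 0.49` stays safely below it — the hub bridges two modules without merging them |
| `planted_mu_mean/sd` | 1.5 / 0.5 | planted structural taxa sit one background-sd above the community mean: the pipeline's own 0.05% abundance filter removes roughly half of median-abundance taxa, and structure must be planted where the network method can see it |
| `cave_sd` | 0.25 | mild cave-level batch structure |
| `noise_sd` | 1.0 | latent residual scale; keeps multinomial noise subdominant at default depth |
| metadata ranges | T 11–25 °C, humidity 80–91%, pH 7.9–8.3 | published karst-cave ranges; pH/TOC/TN are NA for air, moisture only for sediment, mirroring what is measurable per substrate |

Two design points deserve emphasis:

* **Factor centering.** The shared block/hub factors are centered within
  niche groups before use. Without this, a factor's random niche-mean
  (~0.25 sd on the log scale at 32 samples/niche, amplified by the
  heavy-tailed `exp`) hands entire blocks an uncontrolled, randomly
  directed niche preference that can contradict the planted block-niche
  label — the truth file would then mislabel the realized world. Centering
  makes the planted shift the only systematic niche signal for block
  members; within-block correlations are essentially unchanged.

* **False-indicator accounting.** Block members carry a *real* planted
  niche preference, so when IndVal flags one, that is correct behaviour.
  The recovery metric `indicator_false_positive_rate` is therefore
  computed over genera with no planted niche structure; the rate including
  block members is reported separately (`indicator_fpr_incl_blocks`).

What the generator does **not** emulate: sequencing error, chimeras,
compositional bias between niches' library sizes, phylogenetic signal in
abundances (the tree is random, independent of the correlation blocks),
unbalanced designs, and overdispersion beyond the log-normal latent noise.
A green recovery test therefore establishes that the pipeline recovers the
planted statistical structure under multinomial sampling of a log-normal
compositional world — not that it would recover biology from any real
survey.

# Numerical choices

* Permutation p-values use the add-one convention everywhere; minimum
  attainable p is `1/(n_perm + 1)`.
* Ties: Spearman uses midranks; IndVal's argmax group takes the first
  level; keystone ranking breaks betweenness ties by degree then label;
  niche-preference argmax takes the fixed niche order
  (air, water, rock, sediment).
* Permutation-tail comparisons use a `1e-12` slack so exact ties count as
  extreme (conservative).
* Degenerate inputs: all-zero samples error in diversity; all-zero taxa
  are skipped (with a note) in IndVal and enrichment; constant genera give
  NA correlations and can never form edges; empty networks serialize to
  valid zero-edge files but `topology()` refuses them.
* Distance matrices are symmetrized (`(D + t(D))/2`) and validated
  (zero diagonal, non-negativity) at construction.
* All randomness flows from one root seed through `child_seed(seed,
  stage_name)` (a stable string hash mod 2^31 − 1), so any stage can be
  re-run in isolation and reproduce its in-pipeline output.

# Known limitations

* CSS uses a fixed 0.5 quantile (no adaptive selection).
* PERMANOVA is one-way only; no PERMDISP companion, so location and
  dispersion effects are confounded as usual.
* Correlation networks are Spearman-based; no compositionality-aware
  estimator (SparCC/SPIEC-EASI), so strong compositional closure can
  induce spurious negative correlation (mitigated by the positive-edge
  default).
* The run configuration is JSON, not YAML (no YAML parser among the
  package's dependencies).
* Louvain is a stochastic heuristic; determinism is achieved by seeded
  restarts, not by the algorithm itself.
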