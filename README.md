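# strucnet

Phenotype-specific protein–protein interaction (PPI) sub-networks with a
structural overlay, for systems-biology analyses of the kind used to study
organ-specific cancer metastasis: start from a handful of *seed genes* known
to mediate a phenotype, rank every protein of the interactome by
guilt-by-association network propagation, cut out the high-scoring
sub-network, model the three-dimensional interfaces of its interactions from
known two-chain templates, test where those templates come from
(microbial vs non-microbial source organisms), and map point variants onto
the modelled structures as core, surface or interface residues.

The package is tidyverse-native: every stage takes a data frame and returns
a tibble, results chain with the pipe, plots come from `autoplot()`, and
fitted/result objects have broom-style `tidy()`/`glance()` methods.

## The methods in brief

**Prioritization (NetCombo).** Given a network *G* and seed set *S*, three
scores are computed per node and combined:

- *NetScore*: iterative message passing, `s ← (s + mean of neighbour s)/2`,
  seeds pinned at 1;
- *NetZcore*: one propagation pass, z-scored against the same pass on 100
  degree-preserving edge-swap randomizations of *G*;
- *NetShort*: seed-aware shortest paths with edge length
  `1/(1 + seed(u) + seed(v))`, scoring nodes central to the seed set.

Each score vector is standardized, averaged and min–max normalized to
[0, 1]. Edge scores are the mean of the endpoint scores,
`s(u,v) = (s(u)+s(v))/2`, and the sub-network keeps edges with
`s(u,v) > cutoff` (default 0.178). Nodes with degree ≥ 12 are annotated as
hubs.

**Structural overlay.** Two-chain interfaces are residue sets within 5.0 Å
heavy-atom contact distance. Redundant structures are clustered by
single linkage under TM-score > 0.5 and RMSD < 2.5 Å (Kabsch
superposition; TM-score `Σ 1/(1+(dᵢ/d₀)²)/L` with
`d₀ = 1.24(L−15)^⅓ − 1.8`). Template half-interfaces are matched rigidly
onto target chains (accept at RMSD ≤ 2.0 Å, coverage ≥ 0.5), assembled
models are screened for steric clashes, scored with a residue-contact
potential (negative = favorable), filtered at energy < 0, and the
lowest-energy model is kept per interaction.

**Statistics.** Source-organism composition is tested with the upper-tail
hypergeometric probability P(X ≥ k); term enrichment uses the right-sided
hypergeometric test with Holm (Bonferroni step-down) correction at
α = 0.05; location preferences use the two-tailed Fisher exact test.

**Variant mapping.** Full sequences are aligned to structure chains
(residue-level maps rejected below 90% identity); solvent accessibility is
sampled with a rolling probe of 1.4 Å; residues are classified interface →
surface (relative accessibility ≥ 5%) → core, and interface residues that
are buried in the complex with strongly favorable contact energy are
flagged as hot spots.

A synthetic-data module generates every input with known ground truth:
scale-free networks with planted phenotype modules, toy two-chain helix
complexes with exact contact sets, template libraries with controlled
microbial fractions, and variant tables with controlled placement.

## Worked example

```r
library(strucnet)

sim <- gen_network(rng_seed = 42)           # 500 proteins, planted 20-node module
net <- major_component(sim$network)
#> <ppi_network> 500 nodes, 6486 edges

scores <- netcombo(net, sim$seeds, rng_seed = 42)
glance(scores)
#> # A tibble: 1 × 6
#>   method   n_nodes n_seeds n_unresolved min_score max_score
#>   <chr>      <int>   <int>        <int>     <dbl>     <dbl>
#> 1 netcombo     500      10            0         0         1

edges <- score_edges(net, scores)
sub <- extract_subnetwork(net, edges, 0.9)  # strict cutoff for illustration
glance(sub)
#> # A tibble: 1 × 4
#>   n_nodes n_edges average_degree n_components
#>     <int>   <int>          <dbl>        <dbl>
#> 1       6       6              2            1
```

The six nodes surviving a 0.9 edge-score cutoff are all planted-module
members — the propagation scores concentrate on the phenotype module around
the ten seeds. The organism test asks how surprising an observed microbial
chain count is; with the published margins of the lung sub-network (78
microbial of 150 used template chains, against a background of 4918
microbial among 11255 annotated chains):

```r
hypergeom_upper_tail(78, 150, 4918, 11255)
#> 0.02415539
```

i.e. a significant excess of microbial interface architectures (p = 0.024).
Shipped seed lists for the two phenotypes are in
`system.file("extdata", "seeds_lung_metastasis.txt", package = "strucnet")`
(18 genes) and `seeds_brain_metastasis.txt` (17 genes). `run_pipeline()`
executes every stage on synthetic inputs and writes all stage tables plus a
JSON manifest with parameters, seeds and output checksums.

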