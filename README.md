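# miconet

Co-occurrence network analysis of gut-microbiota count tables: SparCC
compositional correlations, keystone-taxon identification, and network
robustness to node removal and addition.

`miconet` is aimed at microbiome researchers who have a genus-collapsed 16S
amplicon count table (plus sample metadata and, ideally, negative extraction
controls) and want to ask *community-structure* questions rather than
taxon-by-taxon ones: How is the co-occurrence network wired in each
experimental condition? Which taxa are keystones? How much targeted damage
can the community absorb before it falls apart — a network proxy for
colonization resistance?

## What it computes

**SparCC correlations.** Sequencing counts are compositional: only relative
information survives, so Pearson correlations on proportions are spurious.
SparCC works from the log-ratio variation matrix

> t<sub>ij</sub> = Var[ log(x<sub>i</sub>/x<sub>j</sub>) ]

which is invariant to the (arbitrary) per-sample total. Under a sparsity
assumption (most taxon pairs uncorrelated), t<sub>ij</sub> ≈ ω<sub>i</sub> +
ω<sub>j</sub> where ω are the latent *basis variances*; solving the linear
system of row sums for ω yields the basis correlations

> ρ<sub>ij</sub> = (ω<sub>i</sub> + ω<sub>j</sub> − t<sub>ij</sub>) / (2 √(ω<sub>i</sub> ω<sub>j</sub>)).

The strongest pair with |ρ| above an iteration threshold (default 0.8) is
excluded from the system and the solve repeated, up to 10 rounds; the whole
estimate is aggregated as the elementwise median over 20
Dirichlet(counts + 1) resamples.

**Networks and keystones.** Taxon pairs with |ρ| > 0.75 become signed,
weighted edges (|ρ| > 0.95 for the core network); isolated taxa are dropped.
Topology reports cover nodes, edges, sign counts, Louvain modularity and
module count, diameter, average and weighted degree, and mean local
clustering. A taxon is a **keystone** of a condition when it is
(i) central — eigenvector centrality ≥ 0.75 (max-normalized, power
iteration on |weight|), (ii) ubiquitous — present in every sample of the
condition, and (iii) abundant — mean clr ≥ 0.35. Both cutoffs are inclusive.

**Robustness.** Node removal under four strategies (random, degree,
betweenness, cascading — betweenness recomputed after every removal) is
scored by *connectivity loss*: the fraction of originally reachable ordered
node pairs rendered unreachable. The headline statistic is the fraction of
nodes that must be removed to reach a loss of 0.80 (random strategy gets a
percentile-bootstrap CI). Node addition attaches new nodes uniformly at
random and traces the largest-connected-component size and average path
length, with Wilcoxon signed-rank + Benjamini-Hochberg statistics per
addition size.

**Supporting stages.** Prevalence-based contaminant flagging against
negative controls (chi-squared score, threshold 0.1), low-abundance
filtering (keep taxa with ≥ 10 total reads AND present in ≥ 30 % of
samples), rarefaction, observed-features alpha diversity, Jaccard beta
diversity with PERMANOVA, and clr-based differential abundance
(Dirichlet Monte-Carlo Kruskal-Wallis, expected p, BH-adjusted).

A synthetic-data module generates count tables with planted, modular
basis-correlation structure (logistic-normal–multinomial), spiked
contaminants and negative controls, so the entire pipeline is testable
without sequencing data.

## Worked example

Plant 15 correlated taxon pairs at |ρ| = 0.9 (6 negative), simulate 300
samples at 5000 reads, and recover the network:

```r
library(miconet)

gt  <- make_basis_network(n_taxa = 30, n_modules = 15, p_within = 1,
                          p_between = 0, neg_frac = 0.3,
                          corr_strength = 0.9, seed = 7)
tab <- simulate_counts(gt, n_samples = 300, depth = 5000, seed = 2)
fit <- sparcc(tab, n_resamples = 20, seed = 3)
net <- build_network(fit, threshold = 0.75)
topology_summary(net)
```

```
SparCC fit: 30 taxa, 300 samples, 20 Dirichlet resample(s)
  median |rho|: 0.040   max |rho|: 0.901   pairs with |rho| > 0.75: 12
conetwork: 24 nodes, 12 edges (9 positive, 3 negative), |rho| > 0.75
network topology
  Nodes                  24
  Edges                  12
  Positive edges         9
  Negative edges         3
  Modularity             0.916
  Modules                12
  Diameter               1
  Average degree         1
  Weighted degree        0.820
  Clustering coefficient 0
```

Twelve of the fifteen planted pairs clear the 0.75 threshold with the right
signs; background pairs stay near zero (median |ρ| = 0.04). The pair modules
reappear as the 12 Louvain modules. Robustness:

```r
attack(net, "cascading")
random_attack_ci(net, n_boot = 100, seed = 4)
```

```
attack_curve [cascading]: 24 nodes; loss >= 0.8 after removing 19 nodes (fraction 0.792)
random removal: mean fraction 0.564 (95% CI 0.458-0.708)
```

On this deliberately fragmented network (12 disconnected dimers) a cascading
attack needs 79 % of the nodes to destroy 80 % of the connectivity — there
are no hubs to exploit. On hub-rich scale-free graphs the ordering reverses
sharply; see the robustness vignette section.

The full pipeline — contaminant removal, filtering, diversity, per-condition
SparCC networks, keystones, robustness battery, differential abundance, and
TSV/GraphML/GEXF/BIOM exports — runs from one config:

```r
cfg <- read_config(system.file("extdata", "config_synthetic.yaml", package = "miconet"))
res <- run_pipeline(cfg, outdir = "miconet_out")
```

A thin command-line wrapper with `simulate`, `run`, `attack` and `report`
subcommands lives at `inst/cli/miconet.R`.

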