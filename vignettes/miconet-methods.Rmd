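---
title: "miconet: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miconet: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miconet)
```

This vignette documents the models behind each pipeline stage, the tunable
parameters and their defaults, the numerical choices that matter for
reproducibility, and what the synthetic-data generator does and does not
emulate.

## The compositional problem and SparCC

A sequencing count table carries only relative information: the library
size is an instrument artifact, so the data live on the simplex.
Correlations computed directly on proportions are distorted by the
closure (every taxon competes for the same total), most visibly as
spurious negative correlation among abundant taxa. SparCC sidesteps the
closure by working with log-ratio variances,

$$t_{ij} = \mathrm{Var}\!\left[\log \frac{x_i}{x_j}\right]
        = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j},$$

which are invariant to per-sample totals. With $D$ taxa and the sparsity
assumption $\rho_{ij} \approx 0$ for most pairs, summing row $i$ gives a
linear system $A\,\omega = t_{i\cdot}$ with $A = (D-2)I + \mathbf{1}\mathbf{1}^{\top}$,
solved exactly by `basis_variances()`. Correlations follow from the
identity above, clipped to $[-1, 1]$.

Assumptions worth keeping in mind:

* **Sparsity.** When many pairs are strongly correlated the row sums are
  contaminated. The iterative exclusion step (below) removes the worst
  offenders, but a densely correlated community will still bias
  $\hat\omega$ and shrink $\hat\rho$.
* **Enough taxa.** The system is unidentifiable below $D = 4$; the
  package refuses such inputs rather than returning noise.
* **Finite depth.** Count noise adds roughly $1/\bar{c}_i$ to the log-ratio
  variance of taxon $i$ with mean count $\bar{c}_i$. Because this inflates
  $t_{ij}$ but (through the diagonal of the solve) inflates $\omega$ less,
  estimates of strong correlations for rare taxa are attenuated toward
  zero. This is a property of the data, not the estimator; the recovery
  test in the acceptance suite quantifies it at the study depth.

### SparCC parameters

| parameter | default | meaning |
|---|---|---|
| `n_resamples` | 20 | Dirichlet resamples; final $\rho$ is the elementwise median |
| `prior` | 1 | pseudocount of the Dirichlet(counts + prior) draw |
| `exclusion_threshold` | 0.8 | per round, the single strongest pair with \|ρ\| above this is excluded |
| `max_exclusion_rounds` | 10 | cap on exclusion rounds |

The exclusion threshold and round cap follow the original implementation's
iteration defaults; both are exposed because the source publication for the
analysis names the method without parameters. Negative solved variances are
floored at $10^{-6}$ so correlations stay defined; a taxon whose every
partner is excluded is dropped from the system and reported via the fit's
`dropped` attribute.

## Networks, topology and keystones

Edges require $|\rho| > 0.75$ strictly (0.95 for the core network), keep
the signed correlation as weight, and isolated taxa are dropped — node
counts therefore refer to connected taxa only. All structural metrics
(modularity, clustering, eigenvector and betweenness centrality) use
$|w|$ or the unweighted skeleton, never signed weights, matching how
desktop network tools handle signed graphs and allowing single modularity
values to be reported.

Numerical choices:

* **Louvain** runs on $|w|$ with a fixed RNG seed (0); module labels are
  reordered by decreasing size, so reports are reproducible.
* **Diameter** is the maximum unweighted eccentricity inside the largest
  connected component (a disconnected graph has no finite global diameter).
* **Clustering** is the mean local coefficient with degree-$<2$ nodes
  contributing 0, so path graphs report 0 rather than NaN.
* **Eigenvector centrality** is computed by power iteration on $|w|$,
  shifted by $+I$ (same eigenvectors; prevents the sign-flip
  non-convergence of bipartite graphs), run blockwise per connected
  component, where the shifted matrix is primitive and convergence is
  guaranteed. The component with the largest leading eigenvalue is
  max-normalized to 1; all other components get exactly 0. This reproduces
  the whole-graph iteration's limit but is immune to the stalling that
  occurs when two components have nearly tied leading eigenvalues —
  a situation the bundled synthetic study actually produces. Tolerance
  $10^{-10}$, cap 1000 iterations, ties between identical components
  resolved deterministically in favour of the first.

A taxon is a keystone of a condition when all three hold: eigenvector
centrality $\ge 0.75$, presence in every sample of the condition, and mean
clr abundance $\ge 0.35$. Both cutoffs are inclusive ("equal or higher"),
which the boundary tests pin down explicitly.

## Robustness simulation

**Connectivity loss** after removing node set $S$ is
$1 - R/R_0$, where $R_0$ counts ordered node pairs mutually reachable in
the intact graph and $R$ counts reachable pairs among survivors; removed
nodes are fully disconnected by definition. This pairwise notion (rather
than, say, relative LCC size) is the one the node-removal literature's
standard tooling implements, and it is verified in the test suite against
exhaustive pair counting on every connected graph with up to 7 nodes.

Attack strategies: `random` (seeded uniform order), `degree` and
`betweenness` (descending, computed once on the intact graph), and
`cascading` (betweenness recomputed on the surviving graph before every
removal). Centrality ties break lexicographically by node id, making all
directed attacks deterministic. The headline statistic is the fraction of
original nodes removed when loss first reaches the 0.80 target; the random
strategy is summarized by the mean and a 2.5/97.5 percentile bootstrap over
independent attack replicates (the cited analysis says "bootstrapping"
without further detail; percentile-over-replicates is the plain reading).

**Node addition** attaches each new node by one edge (configurable) to a
uniformly chosen existing node — previously added nodes included — because
the cited addition method does not specify the rule; preferential
attachment is available as an option. LCC size and APL are recorded after
every addition; APL averages unweighted shortest paths over mutually
reachable ordered pairs and returns NaN when no pair is connected. The
per-size statistics test final-minus-baseline differences with an exact
Wilcoxon signed-rank test (exact enumeration for $n \le 25$ without ties,
normal approximation otherwise; an all-zero difference vector is defined as
$p = 1$), BH-adjusted across the whole (size × metric) family.

## Preprocessing and statistics

* **Contaminant flagging** scores each taxon by the chi-squared statistic
  (no continuity correction) of its control-vs-sample presence table,
  one-sided: the upper-tail probability when the taxon is more prevalent in
  controls, else 1. Taxa scoring below 0.1 (the conventional prevalence
  threshold; the source analysis does not state its value) are removed
  before anything else runs. Degenerate margins (taxon absent everywhere,
  or present everywhere) score 1.
* **Abundance filter**: keep taxa with total reads $\ge 10$ AND prevalence
  $\ge 30\%$ — a literal "strict less-than removal" reading of the
  filtering rule, with both boundary cases (exactly 10 reads, exactly 30 %)
  retained.
* **clr** uses pseudocount 0.5 (the Dirichlet-based tools' convention);
  rows sum to zero by construction.
* **Differential abundance** mirrors the Dirichlet Monte-Carlo design:
  per instance, draw Dirichlet(counts + 0.5) proportions, clr-transform,
  Kruskal-Wallis per taxon; report the expected p over instances (128 by
  default), BH-adjusted across taxa. The inner Kruskal-Wallis is a
  vectorized implementation (tie-corrected), unit-tested against
  `stats::kruskal.test` to machine precision. Note that duplicated
  samples do not produce degenerate $p = 1$ under the Monte-Carlo
  scheme — each copy draws its own proportions — though the point-clr
  statistic is exactly zero there.
* **PERMANOVA** partitions squared distances:
  $F = \frac{(SS_T - SS_W)/(k-1)}{SS_W/(n-k)}$ with
  $SS_T = \sum_{i<j} d_{ij}^2 / n$ and within-group analogues; $p$ uses the
  $+1$-corrected permutation count, so $p = 1/(1+n_\text{perm})$ is the floor.
  The implementation is direct (and cross-checked against vegan's on
  generic data) because the perfectly separated case ($SS_W = 0$,
  $F = \infty$) must resolve exactly: only a group-preserving permutation
  can tie an infinite $F$. All-identical samples ($SS_T = 0$) return
  $F = \mathrm{NaN},\ p = 1$.
* **Jaccard** distance on presence/absence delegates to vegan, with two
  conventions patched in: two empty samples are at distance 0 (identical
  empty sets) and empty-vs-nonempty at distance 1.
* **Rarefaction** subsamples without replacement to the minimum sample
  total by default (the depth used in the source analysis is unreported).

## The synthetic study

The generator emulates the product of a small rodent 16S experiment: four
condition cells (2 groups × 2 timepoints, 8 samples each — the real design
ranges 7–9), 30 genus-level taxa, mean depth 5000 reads with mild
negative-binomial depth dispersion (0.05), two spiked reagent contaminants
present in all four negative controls and ~10 % of true samples at 1–20
reads. Counts come from the logistic-normal–multinomial model — the very
generative model SparCC assumes — with per-taxon log-means uniform on
[0, 3], unit basis variance, and a planted modular correlation structure
(3 modules of 10 taxa, within-module edge probability 0.25, 30 % negative
edges, strength 0.8) that is rewired between groups so the per-condition
networks genuinely differ. Depth 5000 keeps the bundled study small; it is
also the depth at which the recovery guarantees in the test suite are
stated.

Planted target matrices need not be positive semidefinite; they are
projected by clipping negative eigenvalues at 0 and rescaling to unit
diagonal. Two consequences matter for interpretation. First, with dense
conflicting modules the projection can move planted values substantially,
so tests that compare recovered magnitudes against the nominal strength use
configurations that are PSD by construction (disjoint correlated pairs:
$2\times2$ blocks are always PSD). Second, the projected matrix can be
singular, which the multivariate-normal draw handles by an
eigendecomposition square root; matrices with eigenvalues below
$-10^{-8}$ are rejected.

What the generator does **not** emulate: read-level error and chimera
structure, taxonomic misassignment, phylogenetic relatedness (so
tree-based diversity metrics are out of scope), overdispersed zero
inflation beyond what the logistic-normal produces, and batch effects.
Passing recovery tests on this generator therefore demonstrates estimator
correctness under the model SparCC assumes — not performance on arbitrary
real stool data, where depth, dominance and zero structure can be harsher.

## Problem sizes and determinism

The test and acceptance workloads use: 30 taxa × 300 samples for SparCC
recovery; 20 scale-free graphs ($n = 200$, $m = 2$) for the attack-severity
ordering; exhaustive enumeration of the 996 connected graphs on ≤ 7 nodes
(all $2^n$ removal subsets each) for the connectivity-loss oracle; and the
bundled 4 × 8-sample synthetic study for the end-to-end run, whose two
back-to-back executions are compared byte for byte. All randomness flows
from one root seed through per-stage hashed substreams (31-bit safe), so
every stage is independently reproducible; reruns of `run_pipeline()` with
the same config produce byte-identical artifacts, including the manifest
(which records a config hash rather than a timestamp for exactly this
reason).

## Known limitations

* SparCC magnitude estimates attenuate for rare taxa at moderate depth
  (see above); sign recovery is much more robust than magnitude recovery.
* Louvain is seed-pinned for determinism, but different igraph versions
  may still partition differently; modularity values are comparable,
  labels are not.
* The robustness battery's node-addition APL trace is $O(\text{steps} \times
  n(n+m))$; for very large networks set `trace_apl = FALSE` to record only
  the final APL per replicate (all the addition statistics need).
* `compare_networks()` reports intersection-pattern counts as a table;
  drawing UpSet/Venn figures is deliberately left to dedicated tools.
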