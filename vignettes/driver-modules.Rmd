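---
title: "Sample-specific driver modules: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific driver modules: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdriver)
```

## The problem

Tumors accumulate somatic mutations and promoter-methylation aberrations
whose functional impact is heterogeneous across patients: the same altered
gene can perturb different parts of the interaction network in different
individuals. ssdriver characterizes that perturbation **per sample**. It
takes a reference cohort of normal expression profiles, one expression
profile per tumor, gene-level mutation calls, CpG methylation beta values
and an undirected background gene-interaction network (for example
synthetic-lethality pairs), and produces for every tumor a *driver
module*: the part of that sample's co-expression perturbation network that
is reachable from its own altered genes under hub constraints.

## The sample-specific network (SSN)

For each background edge $(i, j)$ the *reference network* carries the
Pearson correlation $\mathrm{pcc}_n$ over the $n$ reference samples.
Adding the single case sample $d$ and recomputing gives
$\mathrm{pcc}_{n+1}$, and the edge's differential correlation is

$$\Delta \mathrm{pcc}_n = \mathrm{pcc}_{n+1} - \mathrm{pcc}_n .$$

Under the null hypothesis that $d$ is drawn from the reference population,
one added observation moves the sample correlation by its influence
function divided by $n + 1$. At the standardized bivariate normal the
influence function is $IF(x, y) = xy - \rho (x^2 + y^2)/2$ with
$\mathrm{E}[IF^2] = (1 - \rho^2)^2$, so

$$\operatorname{sd}(\Delta \mathrm{pcc}_n) \;=\; \frac{1 - \mathrm{pcc}_n^2}{n - 1}
\quad \text{up to } O(1/n^2).$$

A point worth spelling out, because the source literature of this method
family states it loosely: the quantity $(1-\mathrm{pcc}_n^2)/(n-1)$ is the
null **standard deviation** of $\Delta\mathrm{pcc}$, even though it is
often printed as its "variance". Dimensional analysis settles it — the
effect of one observation on a correlation over $n$ samples is $O(1/n)$,
and $(1-\rho^2)/(n-1)$ is $O(1/n)$, so it can only be the scale, not the
squared scale. `edge_statistic()` therefore standardizes as

$$z = \frac{\Delta \mathrm{pcc}_n \,(n-1)}{1 - \mathrm{pcc}_n^2},
\qquad p = 2\,(1 - \Phi(|z|)),$$

and the SSN of sample $d$ is the set of edges with $p < \alpha$
(default $\alpha = 0.01$, no multiple-testing correction — retaining raw
$p < 0.01$ is the method's definition, and `alpha` is exposed for
sensitivity analyses). Had we divided by the square root of that scale
instead, the statistic would be shrunk by a factor $\sqrt{n-1}$ and the
test would retain essentially nothing; the package's null simulations
(`tests/testthat/test-acceptance.R`) check the mean and scale of
$\Delta\mathrm{pcc}$ directly against the formula above.

### Known miscalibration of the normal approximation

$\Delta\mathrm{pcc}$ for a *single* added sample never becomes normal as
$n$ grows: it is distributed as the influence function itself, a
product-normal ("volcano") shape at $\rho = 0$, with heavier-than-normal
standardized tails. The tail mass beyond the two-sided normal 1% cutoff
is about 3.2%, and about 2.7% is observed at $n = 100$ in our null
simulations. The two-tailed Z-test the method prescribes is therefore
mildly anticonservative at $\alpha = 0.01$; we implement the method as
defined and document the true type-I error rather than recalibrating it,
since the downstream constructions (hubs, modules, cohort frequencies)
are defined relative to this retention rule.

### Degenerate edges

Edges with a constant gene in the reference, or with
$|\mathrm{pcc}_n| = 1$, have an undefined or zero null scale; they are
excluded from testing and counted in the returned attributes rather than
assigned $p = 0$. Per-edge sufficient statistics (gene sums, squared sums,
edge cross-products) are precomputed once, so each additional sample's
SSN costs $O(|\text{edges}|)$.

## Omics profiles

**Mutations.** `build_mutation_matrix()` collapses nonsynonymous-mutation
counts to the binary profile $M_{ij} = 1$ iff gene $i$ is mutated in
sample $j$.

**Methylation.** The per-gene profile is built in four steps with the
conventional defaults: probes missing in strictly more than 10% of
samples are removed (a probe missing in exactly 10% is kept);
remaining gaps are filled by 10-nearest-neighbour imputation over probe
rows, with distance the root mean squared difference over co-observed
samples and a row-mean fallback when fewer than $k$ usable neighbours
exist; probes annotated to promoter regions (TSS1500, TSS200, 5'UTR,
1stExon) are consolidated to one value per gene and sample by the median;
and the Hampel filter flags sample $j$ for gene $i$ as hypomethylated
($-1$) when $v < \mathrm{MED} - 3\,\mathrm{MAD}$ or hypermethylated
($+1$) when $v > \mathrm{MED} + 3\,\mathrm{MAD}$, where MED and MAD are
the median and the *unscaled* median absolute deviation (no 1.4826
consistency constant — the rule is the literal formula) of gene $i$
across samples.

Three boundary choices are deliberate: the inequalities are strict, with
a $10^{-10}$ numerical tolerance so a value sitting exactly on a bound is
never flagged by floating-point error; when $\mathrm{MAD} = 0$ (a gene
constant in most samples) any deviation from the median is flagged, and
the per-sample flagged fraction is reported so such genes are visible;
and MED/MAD are computed over the case samples being profiled — whether
tumor-adjacent normals belong in that universe is ambiguous in the
field's usage, so the consolidated matrix passed to `hampel_ternary()` is
whatever the caller assembles, making the alternative a one-line change.
Multi-mapped probes contribute to every gene they annotate.

## Driver modules

Hub genes of an SSN are the top 20% of nodes by SSN degree
(`hub_fraction = 0.20`): the threshold is the degree at rank
$\lceil 0.2\,|V| \rceil$, and ties at that degree are all included so the
result is order-independent. For a sample's seed genes (mutated genes for
ssMutat-DM, aberrantly methylated genes for ssMethy-DM), the module
retains

* seed-to-neighbour edges $(s, u)$ with $u$ a hub, and
* neighbour-to-second-order edges $(u, w)$ with $u$ a hub neighbour of
  some seed and $w$ a hub,

so every non-seed member is a hub and every member lies within graph
distance 2 of a seed. Seeds themselves are exempt from the hub
requirement — altered genes empirically sit at low SSN degree, and
requiring hub status of them would empty most modules. A non-hub
first-order neighbour blocks both its seed edge and any second-order
path through it. The co-driver module (ssCo-DM) is the canonical edge-set
union of the two. A seed–seed edge is retained only when one endpoint
qualifies through the rules above; this case is rare and flagged as a
sensitivity-analysis knob rather than silently decided.

## Cohort and subtype aggregation

Edge frequency is the fraction of samples whose module contains the edge,
over the full background universe (unseen edges count 0). The frequency
cutoff comes from a Monte Carlo null: 10,000 iterations each sample
10,000 edges uniformly (with replacement; a flag switches to without),
take the empirical 95th percentile (type-7 quantile) of their
frequencies, and average the per-iteration cutoffs. The cohort driver
module is the set of edges with frequency **strictly** greater than that
mean cutoff. Subtype modules retain edges present in strictly more than
60% of the subtype's co-driver modules; the shared set is the
intersection across subtypes and the specific sets are the edges in
exactly one subtype's module. Per-sample module sizes by subtype feed the
Kruskal–Wallis and Nemenyi comparisons in `compare_groups()` (the
Nemenyi test is computed from mean ranks against the studentized-range
distribution, without tie correction).

## The synthetic cohort

Every statistical property above is validated on generated data with
known truth; `simulate_cohort()` writes the full fixture set from one
seed, and each generator draws from its own seed stream so adding one
never perturbs another.

* **Background:** preferential attachment (`attachment = 2` edges per
  node), giving the heavy-tailed degree distribution of real interaction
  maps.
* **Expression:** each background edge carries a shared latent
  standard-normal factor; gene $i$ with loading $w_i$ is
  $w_i \sum_e f_e + \sqrt{1 - d_i w_i^2}\,\varepsilon_i$, so an edge's
  latent correlation is $w_i w_j$. A positive-definite construction
  cannot give every edge of a degree-$d$ hub correlation above
  $1/\sqrt{d}$, so by default loadings are capped at $\sqrt{0.9/d_i}$:
  degree-1 genes carry exactly `base_correlation` (default 0.6) and hub
  edges attenuate gracefully; disabling the cap raises an error for
  infeasible requests instead. Values are exponentiated
  ($e^{\mu + \sigma z}$, $\mu = \log 10$, $\sigma = 0.4$) to FPKM-like
  log-normal marginals — at $\sigma = 0.4$ the observed-scale Pearson
  correlation is only mildly attenuated relative to the latent one — and
  a `transform = "gaussian"` option returns the latent scale for
  calibration studies.
* **Perturbations:** a planted perturbation replaces the edge's shared
  factor by $+4$ for one endpoint and $-4$ for the other in the
  perturbed sample only. The pair decouples *and* the sample becomes a
  discordant outlier on that edge; this matters because a merely
  decoupled (but unexceptional) sample moves a correlation over $n$
  samples by $O(1/n)$, which is undetectable against the $O(1/n)$ null
  scale — detectability requires the added sample to be jointly extreme,
  which is also what real tumor decorrelation looks like to this
  statistic. Under these conditions (shift 4, $r = 0.6$, $n = 100$)
  planted edges are detected at roughly 20× the nominal $\alpha$ with
  near-perfect ranking ahead of null edges (ROC AUC > 0.99).
* **Mutations:** i.i.d. Bernoulli (default rate 0.02, the order of
  per-gene nonsynonymous rates in large tumor cohorts) plus forced
  entries.
* **Methylation:** Beta(10, 10) baseline betas — mid-methylated
  promoters, so hyper- and hypo-aberrations are both plantable — with
  3 promoter probes and 1 gene-body probe per gene, planted aberrations
  at beta 0.98/0.02, and a configurable missing fraction.
* **Study sizes:** 400 genes, 100 reference and 50 case samples by
  default; the validation suite scales instances down (tens of genes,
  12–40 samples for oracle checks; 10,000 edge-tests for calibration) so
  the whole suite runs in well under a minute.

What passing these tests shows — and does not. The generator reproduces
the *statistical structure* the method assumes: known edge correlations,
single-sample perturbations, binary mutations, beta-valued methylation
with outliers, scale-free topology. It does not emulate realistic
breast-cancer effect sizes, subtype-structured biology, copy-number or
fusion events, batch effects, or correlated mutation/methylation
processes; recovery on these fixtures validates the machinery, not any
clinical claim.

## Numerical and design choices

* Edges are undirected and stored canonically (lexicographic endpoint
  order) everywhere; loading a shuffled edge list yields an identical
  graph, and serialization is byte-stable, which is what makes the full
  pipeline rerun byte-identical under a fixed seed.
* Gene identity is the bare case-sensitive symbol; users must harmonize
  symbols across omics files beforehand.
* Missing expression values drop the gene row (never imputed);
  methylation is the only imputed data type.
* Betweenness is reported unnormalized (a 5-node star's center scores
  exactly $(n-1)(n-2)/2 = 6$, the closed form used in tests);
  normalization is a flag. Eigenvector centrality is computed per
  connected component — modules are often disconnected — and normalized
  to unit maximum within each component.
* Jaccard similarity of two empty sets is 0 with a warning (it occurs
  for samples with empty modules).
* Both empty-input directions are first-class: `alpha = 0` produces
  empty SSNs, empty modules and a clean pipeline run; subtypes whose
  modules are all empty yield empty subtype modules rather than errors.
* The Monte Carlo cutoff seed is part of the provenance record the
  pipeline writes next to its outputs.

## Limitations

The Z-test's true type-I error at $\alpha = 0.01$ is ~3% (see above), so
SSN edge counts are comparable across samples but not literal
false-positive rates. The kNN imputation is $O(\text{missing} \times
\text{probes})$ and intended for the post-filter missingness regime
(≤10% per probe), not for wholesale reconstruction. The U-test variant
of the edge test and differential-methylation calling against normals
are out of scope.
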