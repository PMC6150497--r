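---
title: "Anchored gene-network expansion: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anchored gene-network expansion: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Genome-scale network inference from a few dozen expression profiles is
drastically under-determined: global searches return thousands of candidate
edges, most of them false. `bakenet` implements the opposite strategy — a
*locally anchored* search. It starts from a pathway that is already known
(curated from databases and literature), identifies which of its members
respond to the experimental contrast ("anchor" genes), and then asks a much
smaller question: which differentially expressed genes co-vary so tightly
with the anchors, across all experimental conditions, that they behave like
members of the same regulatory neighbourhood?

The pipeline has five stages, run end-to-end by `run_bake()`:

1. **Candidate discovery** (`moderated_t_test()`, `sam_test()`,
   `intersect_de()`): probes differentially expressed between two
   conditions, called by *both* an empirical-Bayes moderated t-test and a
   SAM-style permutation test at the target FDR. Two dissimilar tests
   intersected is a deliberate false-positive filter.
2. **Known pathway** (`read_gene_set()`, `resolve_gene_set()`): the curated
   gene list resolved to probes. All computation is probe-level; gene
   symbols are annotations.
3. **Association screen** (`spearman_matrix()`, `pathway_score()`,
   `background_pool()`, `resampled_roc_threshold()`, `select_L1()`):
   candidates are scored by their top-5% Spearman correlation to the
   pathway across *all* samples pooled; the significance threshold is
   chosen by resampled ROC curves against random pathway surrogates,
   maximizing Youden's J.
4. **Network expansion** (`top_neighbors()`, `assemble_distance()`,
   `spc_profile()`, `t_critical()`, `stable_clusters()`, `infer_edges()`):
   around each anchor probe, the top correlated candidates are clustered
   together with the anchors by superparamagnetic clustering (SPC) along a
   temperature gradient; clusters surviving above a permutation-calibrated
   critical temperature, containing at least one anchor and at most one
   novel gene, become network edges.
5. **Reverse confirmation** (`reverse_confirm()`): each novel gene is used
   as a new anchor; the original anchor must reappear among its top
   neighbours (the correlation is symmetric, the neighbourhood need not
   be).

A hidden-gene benchmark (`hidden_gene_split()`, `benchmark_run()`,
`score_recovery()`) withholds part of a known network and scores whether
expansion around the remaining anchors rediscovers the withheld members,
reporting sensitivity, specificity and positive predictive value at both
probe and gene level (the two denominators differ when genes carry several
probes; both are reported).

# Statistical components

## Moderated t-test

Per probe, the pooled two-group variance $s_g^2$ (df $d_g$) is shrunk
toward a prior fitted by method of moments to a scaled
inverse-$\chi^2$ law on the log scale:
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$, and
$\tilde t_g = \Delta_g / (\tilde s_g \sqrt{1/n_a + 1/n_b})$ is referred to
$t_{d_0+d_g}$. `d0 = 0` recovers the classical equal-variance t exactly
(this is a frozen unit test); the fitted version tracks `limma::eBayes` to
high accuracy, which the test suite uses as an independent oracle. With
5–9 samples per group, variance moderation is what makes per-probe testing
usable at all.

## SAM-style permutation test

The regularized score $d_g = \Delta_g/(se_g + s_0)$ uses the
variance-stabilizing fudge factor $s_0$ chosen by the canonical
minimum-CV rule over percentiles of the per-probe standard errors. Sample
labels are permuted (all distinct assignments are enumerated when fewer
than `n_perm` exist — at $n=5{+}9$ there are 2002); probes are called at
the smallest distance $\Delta$ from the expected order statistics whose
estimated FDR, $\hat\pi_0 \cdot \overline{\mathrm{false\ calls}} /
\mathrm{calls}$, is at or below the target. We summarize per-permutation
false-call counts by their **mean**: the more traditional median collapses
to zero whenever a $\Delta$ admits only one or two calls, which lets null
data through at "FDR 0" — on all-noise matrices the median rule produced
spurious calls in roughly a third of runs, while the mean rule is cleanly
calibrated (`false_stat = "median"` restores the old convention).
Anchor selection uses raw permutation p-values from the pooled null of
$|d|$, jointly with the moderated-t p-value, both at `anchor_alpha`.

## Association screen and threshold

Correlation uses Spearman's rank coefficient over all samples pooled
across conditions — association here *means* "responds to the condition
series with the same shape", and rank correlation is insensitive to probe
scale. Each candidate is summarized by its top-5% correlation to pathway
probes with the nearest-rank (ceiling) convention: for 80 pathway probes
that is the 4th-largest coefficient. A gene needs only a handful of strong
pathway partners to qualify, which is the right notion when pathways are
heterogeneous collections of sub-complexes.

The threshold on this summary is data-driven: candidates are also scored
against `n_resamples` random "pathways" of the same probe count, drawn
from a background pool that excludes anything differential in *any*
pairwise condition contrast. Per resample, an ROC curve over the union of
observed scores yields the smallest threshold maximizing Youden's
J = TPR − FPR (ties resolved toward the smaller, more inclusive
threshold); the final threshold is the median across resamples. Signed
correlations are used (an `absolute` flag exists): positive co-variation
is the association the method interprets.

## Superparamagnetic clustering

SPC treats each probe as a q-state Potts spin on a k-nearest-neighbour
graph (union connectivity, `k = 10`) built from the correlation distance
$D = 1 - \rho$. Couplings are
$J_{ij} = \frac{1}{\hat K} \exp(-D_{ij}^2 / 2a^2)$ with $\hat K$ the mean
degree and $a$ a local distance scale. Swendsen–Wang sampling (freeze
agreeing edges with probability $1 - e^{-J_{ij}/T}$, flip frozen
components to uniform random states) estimates the pair correlation
$G_{ij} = (q\,\mathrm{freq}(s_i{=}s_j) - 1)/(q-1)$; clusters are connected
components of edges with $G > 0.5$. At $T = 0$ everything is one cluster
(written analytically); as $T$ rises clusters shed weakly coupled members
and finally dissolve. Cluster *persistence* — the longest consecutive
temperature run over which exactly the same member set appears — measures
association strength; duplicate probes of one gene, when present, form the
longest-surviving pairs, a built-in positive control.

Numerical choices, all config-exposed in `spc_params()`:

* **Local scale `a` = mean distance over the kNN edge set.** A scale set
  by each point's *single* nearest neighbour collapses to the
  duplicate-probe distance on expression data (platforms carry several
  probes per gene), exponentially suppressing every other coupling; the
  neighbourhood average keeps tight pairs tight *relative to the bulk*,
  which is what the clustering needs to resolve.
* **`q_states`** (Potts states): higher q sharpens the transition but
  suppresses small-cluster order (a pair needs $J/T > \log(q-1) \cdot
  {\sim}1$ to cohere); the default balances the two so that 3–8-probe
  clusters — the size the expansion step interprets — survive over a
  readable temperature window on the fixed 0–1 grid.
* **`sweeps` / `burn_in`**: 250/50 by default; the pair-correlation
  estimator was validated against exhaustive Boltzmann sums on a 4-node,
  q=3 toy (exact enumeration of all 81 states, batch-means error bars).
* **Temperature grid** 0 to 1 in steps of 0.01, `k = 10`: the published
  operating point.
* Each temperature runs an independent chain with a deterministic random
  stream derived from `(seed, temperature index)` — profiles are
  reproducible and independent of evaluation order.

## Critical temperature

Observed structure is only meaningful above the temperature at which
*random* data stop clustering. For each of `n_null_permutations`
replicates, every probe's expression vector is permuted independently
across all samples (destroying correlation, preserving marginals), the
distance matrix and its SPC profile recomputed, and the maximum cluster
size per temperature recorded. $T_{critical}$ is the lowest grid
temperature at which the observed maximum exceeds the null mean by
`z_threshold` null standard deviations (z = 2 by default; the reference
analysis displays mean ± SD, so "significantly higher" is operationalized
as a 2-SD exceedance), *sustained over `min_consecutive` grid
temperatures* (2 by default). The sustained-exceedance requirement is the
multiplicity control: a pointwise z = 2 rule applied independently at ~100
grid temperatures fires on unstructured data far too often (measured:
30–40% of pure-noise runs), whereas genuine structure keeps the observed
maximum above the null over a contiguous temperature window — "the
temperature beyond which" the observed and random clustering patterns are
distinct. With both defaults the rule is cleanly calibrated: on
permutation-generated input it stays undefined in ~100% of runs while
detecting a planted 8-probe block in ~100%. When the null SD is zero
everywhere the rule falls back to strict exceedance of the mean.
If no temperature qualifies,
$T_{critical}$ is undefined and the run contributes no clusters — on
permutation-generated input this is the common outcome, which is exactly
the desired null calibration.

## Cluster selection and edges

Above $T_{critical}$, member sets are classified: kept if they contain at
least one anchor probe and at most one novel *gene* (several probes of one
novel gene count once — the duplicate-probe clusters are confirmations,
not violations); excluded when novel-only or multi-novel. Kept clusters
contribute all within-cluster pairs as edges, typed anchor–anchor or
anchor–novel, annotated with the pair correlation and the cluster's
persistence span; the same pair found in several runs keeps the maximum
span. Edge sets are invariant to anchor processing order, and emitted
files are canonically ordered (SIF/GraphML/TSV writers).

Per-run geometry follows the published recommendation: about 40 probes
per clustering, half anchors. When more anchor probes pass the filter than
fit, each run clusters its focal anchor plus the most significant others
up to `l_total / 2`, and one expansion is run per anchor probe, so every
anchor gets a neighbourhood.

# The synthetic-data generator

`simulate_expression()` emulates the study design the method targets: four
diet/time conditions with small groups (DC8 n=7, DW8 n=5, DC16 n=5, DW16
n=9), a planted pathway whose members share condition-driven latent
activity, planted novel genes on the same activity (the discovery
targets), and a large independent background. Probes are the unit:
`probes_per_gene = 2` by default, mirroring expression platforms
(the reference platform carries ~45k probe sets for ~20k genes; duplicate
probes are also what makes the clustering's positive control available).

Two structural features matter and are worth stating plainly:

* **Sub-modules.** Pathway genes fill modules of `module_size`; associated
  genes join modules round-robin. Genes load on their module's latent
  activity $b_{ms} = \mu_{m,c(s)} + \sqrt{w}\,\eta_s + \sqrt{1-w}\,u_{ms}$
  with loading $\lambda$ = `latent_strength`:
  $x_{gs} = \mathrm{baseline}_g + \mathrm{noise\_sd}\,(\lambda b_{ms} +
  \sqrt{1-\lambda^2}\,\varepsilon_{gs})$. A single global factor (the
  simplest conceivable model, recovered with `module_coherence = 1` plus a
  shared `condition_effects` vector) makes every planted pair *equally*
  correlated — a structure superparamagnetic clustering rightly refuses to
  subdivide, and whose permutation null it cannot beat. Real pathways are
  organized in sub-complexes whose members co-express far more tightly
  than the pathway at large (mTORC1 components, PI3K/AKT effectors, and
  duplicate probes, in the motivating data); the module structure
  reproduces that two-scale geometry.
* **Diverse condition-response profiles.** Each module draws its own
  response shape across conditions (`N(0, (de_log2fc/2)^2)` per
  non-contrast condition), with the DW16−DC16 contrast pinned to
  ±`de_log2fc` (sign alternating by module — real anchor sets contain both
  up- and down-regulated genes). One shared response shape would make all
  differentially expressed genes rank-correlate strongly regardless of
  module, erasing the distinction the association and clustering stages
  exist to find.

Default effect sizes are chosen once, as study conditions: `de_log2fc = 4`
on the latent scale gives gene-level shifts of $\lambda \cdot 4 = 3.2$
log2 units — the magnitude of the strong diet-responsive genes that anchor
the real analysis, and comfortably detectable at 1% FDR with n = 5–9;
`latent_strength = 0.8` puts within-module correlations near 0.9 and
cross-module correlations in the moderate range; `noise_sd = 1` and
`probe_noise_sd = 0.5` place duplicate-probe correlations around 0.93,
typical of distinct probe sets of one gene.

What the generator does **not** emulate: batch effects, probe
cross-hybridization, intensity-dependent variance, outlier samples, and
the long-tailed module-size distribution of real pathways. Tests passing
on this generator show the pipeline recovers *planted* two-scale
correlation structure at realistic n; they do not certify performance on
any particular real dataset.

# Reproducibility and problem sizes

Every stochastic stage takes a seed and derives child seeds
deterministically; `run_bake()` is bit-reproducible given its seed.
One exactness-preserving shortcut is worth knowing about: because
row-wise permutation reduces Spearman correlations to functions of
independent uniform rank orderings, the permutation null of the
max-cluster-size trace depends only on the item count, sample count and
clustering parameters — `run_bake()` therefore draws that ensemble once
(`spc_null_max()`) and shares it across anchor runs of identical
geometry, instead of permuting each run's expression rows; standalone
`t_critical()` calls still permute the actual data. The
test-suite and acceptance problem sizes — 2,000 probes, 26 samples, 50
ROC resamples, 50 null permutations with 100 sweeps per temperature — are
desk-scale choices that keep a full 20-seed replication within minutes
while leaving every qualitative behaviour (threshold location, critical
temperature, recovery rates) in the same regime as the defaults
(100 resamples/permutations, 250 sweeps).

# Known limitations

* Edges are undirected; static condition-series correlation cannot resolve
  direction, feedback loops, or synergistic regulation.
* The association screen is one-dimensional (pairwise correlation); genes
  associated with the pathway only through interactions invisible to rank
  correlation are missed.
* $T_{critical}$ compares maximum cluster sizes only; a structured dataset
  whose largest cluster happens to match the null's giant component size
  at every temperature would be declared unclusterable.
* The hidden-gene benchmark's specificity depends on the declared
  candidate universe (the differential-expression pool minus anchors);
  universe choices are explicit and configurable because a specificity
  without a universe is meaningless.
* Whether sample-label permutation nulls should respect condition
  structure is a real modelling choice; profiles are permuted across *all*
  samples, matching the global-correlation reading of the association
  screen.
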