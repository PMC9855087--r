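---
title: "Ranking drug targets over a mechanistic signaling map: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking drug targets over a mechanistic signaling map}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kdtrank)
```

## The problem

In diseases driven by dysregulated signaling — the motivating case is
retinitis pigmentosa, with the lipid-mediator enzymes ALOX5 and ELOVL4 as
candidate targets — one wants to rank *known drug targets* (KDTs, genes with
at least one approved or annotated drug) by how much regulatory influence
they exert over the disease's signaling circuitry. kdtrank implements that
ranking as a pipeline: mechanistic circuit activities from expression, a
multi-output random forest from KDT expression to activities, Shapley
attribution, an R²-gated selection rule, and a stability assessment.

## Circuit activity model

A *circuit* is a directed acyclic receptor→effector subgraph whose nodes
carry one or more gene symbols. Expression is first normalized per gene:
values are truncated at the gene's `upper_quantile` quantile (default 0.99,
blunting outliers so that a single extreme sample does not compress
everything else toward 0) and min–max scaled to [0, 1]. A gene constant
across samples maps to all zeros — the deterministic convention that a flat
profile carries no signal; the alternative (0.5) would inject spurious
half-activation into every circuit containing such a gene.

Node values aggregate bundled genes (mean by default; min available for
AND-like complexes). Signal then propagates in topological order:

$$S_n = v_n \cdot \Big(1 - \prod_{a \in A}(1 - S_a)\Big) \cdot \prod_{i \in I}(1 - S_i)$$

with $S = v$ at receptors (full incoming stimulus) and activation factor 1
when a node has only inhibiting parents. This probabilistic OR / AND-NOT
rule is the standard signal-propagation convention for mechanistic pathway
activity models. Two consequences are load-bearing for tests: on a pure
activation chain the activity is exactly $\prod_i v_i$, and a zero anywhere
on the chain is absorbing. Cyclic circuits are rejected at validation rather
than iterated to a fixed point: determinism and testability outweigh
coverage of feedback loops at this scale.

Numerical note: with a single activating parent the activation factor is
taken as $S_a$ directly rather than $1-(1-S_a)$, which differs by an ulp in
floating point; this keeps the chain closed form *bit*-exact.

## Relevance model and attribution

The feature matrix X is the expression of the KDT list only — the scientific
question is a ranking *of the KDTs*, not a genome-wide screen. One
multi-output random forest predicts all circuit activities jointly; every
split maximizes the variance reduction summed over outputs. Defaults:
500 trees, mtry = ⌈d/3⌉, unlimited depth, minimum node size 5 (a common
regression compromise that bounds tree size without materially affecting
rankings). The forest is implemented in the package's own C++ with a
deterministic splitmix-style generator, so fits are bit-reproducible across
platforms given the seed.

Per-circuit predictability is the out-of-fold R² from a seeded K-fold
cross-validation (K = 5). Cross-validation was chosen over out-of-bag
scoring because it is selector-agnostic, cheap at this scale, and exactly
reproducible from the fold seed; a constant response gets R² = 0 by
convention (no variance to explain). R² can be negative — worse than the
mean predictor — and the selection stage clips it at zero.

Shapley values are computed in *interventional* mode against an explicit
seeded background (default min(100, n) training rows): the value of a
coalition S is the background-mean prediction at the hybrid point taking
features in S from the sample and the rest from the background row. For a
tree ensemble this is computed **exactly**, per (sample, background) pair,
by enumerating for each leaf the features whose split constraints only the
sample satisfies (set A) or only the background satisfies (set B); the
indicator game $1[A \subseteq S, B \cap S = \emptyset]$ has a closed-form
Shapley value. Two properties follow and are asserted in tests: local
accuracy ($\sum_f \phi_f + \text{base} = \text{prediction}$ to machine
precision) and equality with brute-force coalition enumeration on small
models. relevance(g, c) is the mean |φ| across samples (not the sum:
sample-size invariance), and the global score is the mean across circuits;
ranks break ties by gene symbol so output is deterministic.

## Selection rule

The printed anchors of the method are: a perfectly predicted circuit keeps
its top 5% of KDTs, and the kept fraction shrinks as predictability drops.
The implementation is the convex combination of quantiles
$q = \mathrm{clip}(r^2)\,0.95 + (1-\mathrm{clip}(r^2))\cdot 1$, i.e. a
selected fraction $0.05\,\mathrm{clip}(r^2,0,1)^\gamma$ with γ = 1 by
default; the exponent is exposed because "a convex formula" admits a family
of interpretations, and γ > 1 gives a more conservative gate without
changing either anchor. The count is `floor(fraction × n_kdts)`, so poorly
predicted circuits select nothing — deliberately conservative. No additional
hard R² threshold drops circuits: the clip at zero is the only gate, since
the gradual shrinkage already starves unpredictable circuits.

A practical corollary worth knowing: with few KDTs the floor makes the rule
coarse (40 KDTs need r² ≥ 0.5 to select even one gene), and a pipeline whose
responses are pure noise selects *nothing* anywhere. The stability estimator
is then undefined (mean selection size 0) and is reported as such with a
reason, never as a number.

## Stability

Given the M × d binary selection matrix Z (rows = refits on seeded 80%
subsamples; one vector per resample, by default the union of selected KDTs
over circuits — a per-circuit mode keeps one block of columns per circuit),
the Nogueira estimator is

$$\hat\Phi = 1 - \frac{\tfrac1d\sum_f s_f^2}{\tfrac{\bar k}{d}(1 - \tfrac{\bar k}{d})},
\qquad s_f^2 = \tfrac{M}{M-1}\,\hat p_f(1-\hat p_f).$$

Φ̂ = 1 iff all resamples agree; it is ≈ 0 for random selections of the same
sizes, and can be negative for anti-correlated ones (the alternating
two-feature example gives exactly −1/9 at M = 10). The 95% CI is a
percentile bootstrap over the M rows (default 1000 replicates, degenerate
replicates skipped and counted) rather than the asymptotic variance: it is
self-contained, and its behavior (collapse on identical rows, shrinkage
with M) is directly testable. The *effect size* — not defined in the
method's source — is Φ̂ minus the mean Φ̂ of a matched null that redraws
each row's selections uniformly at random with the same per-row counts
(500 draws).

## What the synthetic generator emulates — and what it does not

The generator stands in for a tissue-expression compendium over a curated
disease map. A collection of chain/branched DAG circuits is built; each
planted *driver* KDT is placed solo into a node of up to two circuits;
roughly a third of the decoy KDTs are bundled into multi-gene nodes (the
mean aggregator dilutes them into weak, genuinely causal signals); the rest
appear in no circuit. Expression is baseline + signal + noise, truncated at
zero, with Gaussian marginals.

One modeling choice deserves emphasis. Per-gene min–max normalization
erases amplitude, so "drivers have higher variance" cannot by itself make
drivers matter downstream. What makes KDT-restricted features predictive of
circuit activity in real tissue data is *co-expression*: pathway genes are
co-regulated with their upstream drivers. The generator therefore gives each
circuit's structural genes loadings (U(0.5, 1)) on the mean latent factor of
that circuit's drivers (or on a circuit-private latent when it hosts none),
scaled by the effect multiplier (strong/moderate/weak → 3.0/1.5/0.5;
a numeric override of 0 plus `noise_sd = 0` yields a fully constant world).
Consequences: driver circuits are predictable from X (R² ≈ 0.5–0.75 at
realistic forest sizes), driverless circuits are not (R² ≈ 0), and planted
drivers dominate the global ranking through the propagation rule alone — no
label leakage.

What a green test therefore establishes: the pipeline recovers planted
upstream drivers from co-expression structure transmitted through the
propagation rule, ranks them above diluted and null decoys, and selects them
stably across subsamples. What it does **not** establish: performance under
real-data pathologies the generator deliberately omits — tissue and batch
structure, heavy-tailed expression, correlated decoys, feedback loops, or
the topology of any real disease map. The source study's absolute relevance
figures are likewise out of reach without its external inputs, which is why
acceptance rests on worked examples and properties, not on reproducing those
numbers.

## Numerical and design choices, collected

- Defaults stated once: 40 KDTs / 5 drivers / 20 circuits / 300 samples,
  noise SD 0.25 against signal amplitude 3.0 (strong) — chosen as a
  desk-scale version of a 125-KDT disease map, dimensioned so the floor-based
  selection rule remains non-trivial.
- Seeds: one user seed, fanned out per stage by a counter-based derivation
  (`derive_seed`), recorded in the run manifest; all C++ randomness uses a
  standard-library-free generator for cross-platform bit-reproducibility.
- Ties: ranking and selection break ties by gene symbol ascending;
  thresholds split at value midpoints.
- Degenerate inputs: constant genes normalize to 0; constant responses get
  R² = 0; empty/full selections make Φ̂ undefined-with-reason; cyclic or
  unreachable circuits fail validation with the circuit named.
- Config files are JSON (no YAML parser in the supported dependency set).
- Dose tables: doses are `rate × content / 100`, rounded half-away-from-zero
  to 3 decimals for display; class totals are summed *before* rounding. The
  bundled composition table encodes the source batch sheet's own class
  grouping, including its two idiosyncrasies (Adrenic outside the ω-6 total,
  Eicosatetraenoic outside the PUFA total), so printed totals reproduce
  exactly.

## Known limitations

Circuits must be DAGs; multi-gene node aggregation is mean/min only; the
forest has no hyperparameter search (deliberately — the method's claims are
about attribution and selection, not about squeezing R²); interventional
SHAP cost grows with background size × samples × trees, so scaled-down
backgrounds are advisable for exploratory loops; and the stability CI is a
row bootstrap, which undercovers for very small M.
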