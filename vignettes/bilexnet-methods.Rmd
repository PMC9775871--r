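---
title: "Lexical networks and repetition priming: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lexical networks and repetition priming: models, choices, limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bilexnet)
```

bilexnet implements two analysis arms that together characterise a bilingual
(or bidialectal) mental lexicon: a **network arm** that turns semantic-fluency
responses into word-correlation graphs and asks whether they are small-world
and modular, and a **priming arm** that analyses long-term cross-language
repetition-priming reaction times with mixed-effects models.  This vignette
is the package's own account of the models, the tunable parameters, the
numerical choices, and what the synthetic generators can and cannot tell you
about real data.

## The network arm

### From fluency responses to a weighted graph

A semantic fluency task yields, per participant, an ordered list of words
from one category (say, animals) in one language.  `build_incidence()`
collapses these lists into a binary **incidence matrix**: one row per
participant, one column per distinct word anyone produced, cell = 1 iff that
participant produced that word.  Word order and within-participant
repetitions are deliberately discarded — the network is built from *who
produces what*, not from production order.

`word_correlations()` then correlates word columns across participants.
For binary data the default Pearson correlation is the phi coefficient; two
words correlate positively when the same participants tend to produce both.
Words produced by everyone (or no one) have zero variance and an undefined
correlation.  The default policy keeps such words as nodes with all their
correlations set to zero, because the node set should remain the produced
vocabulary; `zero_variance = "drop"` removes them instead.

`build_network()` makes the weighted undirected graph.  The default edge
policy keeps **every** finite off-diagonal correlation — a near-complete
graph.  This default is chosen deliberately: clustering coefficients near
0.98 and hop path lengths near 1.02, the regime reported for empirical
fluency networks of 40–55 words, are only attainable on a near-complete
graph (any tree, by contrast, has clustering exactly 0).  A `"positive"`
policy and a `τ`-threshold policy are available for sparser backbones, and
`spanning_tree()` provides the classic maximum-similarity spanning tree
(equivalently, the minimum spanning tree on the 1 − r distance).  Because a
"minimal spanning tree with minimum total edge weight" and "keeping the
strongest relations" pull in opposite directions on similarity weights, both
objectives are implemented; the default is `max_similarity`, and the metric
report defaults to the full weighted network, not the tree.  Spanning-tree
ties are broken lexicographically by node pair, so results are fully
deterministic.

Negative correlations are retained by default (no sign filter is applied to
edge weights).  Two consumers cannot use them: Barrat's weighted clustering
and modularity maximisation are defined for nonnegative weights, so weighted
clustering refuses negative weights with an explicit error (and
`network_metrics()` falls back to unweighted clustering with a warning),
while `detect_communities()` drops negative edges with a message before
optimising.

### Network statistics

* `clustering_coefficient()` — mean local clustering; unweighted
  (Watts–Strogatz) or weighted (Barrat).  Nodes of degree < 2 contribute 0
  rather than being excluded; this is a stated convention because it changes
  the mean.
* `average_shortest_path_length()` — mean shortest-path length over
  unordered pairs; `"hops"` (default) or `"weighted"` with the 1 − r
  distance.  Disconnected graphs are reduced to the largest component with
  a warning.
* `small_world_index()` — S = (CC/CCran)/(ASPL/ASPLran), with the
  denominators taken from a size-matched random-graph ensemble; S > 1 is
  the small-world classification.
* `modularity_score()` — Newman–Girvan Q computed directly from its
  definition; `detect_communities()` maximises it with seeded Louvain, or
  exhaustively over all set partitions for ≤ 10 nodes.  The reported Q is
  always recomputed from the returned assignment, never trusted from the
  optimiser.

The default report modes — weighted CC, hop ASPL — are the pair that keeps a
near-complete correlation graph informative: hop path length saturates near
1 on such a graph, while Barrat clustering still varies with the correlation
structure.  Every report records the modes actually used.

### The Erdős–Rényi null

`null_ensemble()` draws G(n, p) graphs (default p = 0.5, 1000 replicates)
matched to the empirical node count exactly, and records unweighted CC, hop
ASPL on the largest component, and Louvain Q per replicate.  The ensemble
means supply CCran and ASPLran for the small-world index.

`compare_to_null()` runs a one-sample t test of the ensemble values against
the empirical value (df = reps − 1) and reports the z score
(empirical − mean)/SD.  These answer different questions: the t statistic
asks whether the *null mean* differs from the empirical value and grows with
√reps — with 1000 replicates it is nearly always enormous — while the z
score asks whether the empirical network could plausibly have been drawn
from the null, and is the quantity that is calibrated (|z| > 1.96 about 5%
of the time under the null; the package tests this property).
`pooled_null_comparison()` additionally pools deviations across several
networks into one t test per metric, for a single family-level statement.

A caution the package makes explicit: at p = 0.5 the expected ER clustering
coefficient is ≈ 0.5, so published null baselines near 0.94–0.97 cannot come
from unweighted clustering on plain ER graphs; the ER implementation here is
therefore validated against binomial theory (ensemble mean CC → p, edge
count → Binomial(n(n−1)/2, p)), not against any published baseline column.

## The priming arm

### Filters

The preprocessing chain is participant filter → correct-only → trimming →
log transform, in that order, and each stage is idempotent:

1. `filter_participants()` removes all trials of subjects whose overall
   accuracy is *strictly below* 80% (the boundary case is retained).
2. `preprocess_rt()` drops incorrect trials, then removes — in a single,
   non-recursive pass — trials beyond ±2.5 SD of the mean within the
   trimming scope, then adds `log_rt = ln(rt_ms)`.  Trimming operates on the
   millisecond scale, before the log transform.

The trimming scope is exposed because it changes which trials are removed
and the convention is genuinely unsettled in RT research: the default
`"cell"` (subject × language condition × stimulus type — the design cell)
is the dominant modern convention; `"subject"` and `"global"` are provided
as alternatives.  A scope cell with fewer than two correct trials is left
untrimmed with a warning rather than silently dropped.

### The mixed model and backward selection

Per language condition, `fit_priming_model()` fits

    log_rt ~ stimulus_type + (1 + stimulus_type | subject) + (1 + stimulus_type | item)

with stimulus type treatment-coded, unlearned as reference.  Under this
coding the coefficient is the learned-item shift on the log scale, so
**facilitation appears as a negative coefficient and a positive millisecond
priming effect** (mean unlearned − mean learned).  The two sign conventions
are sometimes conflated in published tables; the package keeps the
mathematically consistent pairing and reports both the coefficient and the
millisecond effect.

The random structure is selected backwards from the maximal model.  At each
step every admissible single reduction is fitted by maximum likelihood —
correlations may go first, then a slope whose correlation is gone, then an
intercept whose slope is gone — and the reduction with the largest
likelihood-ratio p value is adopted when p > α (default 0.05); an AIC mode
is available.  Likelihood-ratio tests of variance components sit on the
boundary of the parameter space and are therefore conservative, which only
biases the procedure toward *retaining* random terms — the safe direction.
If every random term is removed the model collapses to ordinary least
squares, where, in a balanced design, the stimulus-type estimate equals the
plain difference of cell means (a property the tests assert to 1e-6).  The
selected structure is refitted by REML for reporting, with Satterthwaite
degrees of freedom from lmerTest.  If the maximal model fails outright, the
fit walks down a fixed simplification ladder and records the fallback.

## The synthetic generators

The raw fluency and trial data behind the published analyses are not
deposited, so the package ships generators that reproduce the *statistical
structure the analyses assume*, making every downstream stage testable.

`simulate_fluency()` uses a planted-cluster Bernoulli model: the vocabulary
is partitioned into latent semantic clusters; each participant knows a fixed
number of clusters and produces each word of a known cluster with
probability `p_within` and every other word with probability `p_between`.
Defaults — 32 participants, 45 words in five clusters of nine, three
clusters per participant, p_within = 0.9, p_between = 0.05 — emulate a
fluency study with ~32 participants and a 40–55 word vocabulary.  Cluster
assignment is sampled without replacement so that expectations stay
analytic, and the realised assignments are attached to the dataset so tests
can recompute exact binomial expectations.

`simulate_rt()` is lognormal with additive Gaussian subject and item
intercepts on the log scale, a fixed learned-item shift, and independent
Bernoulli correctness — mirroring the analysis model exactly, so parameter
recovery is well-specified.  Defaults (32 subjects, 20 items per cell,
grand mean 6 log-ms ≈ 403 ms, shift −0.12, SDs 0.2/0.1/0.3, accuracy 0.95)
emulate the published design's cohort sizes and effect scale.

What the generators deliberately **do not** emulate: production order and
retrieval dynamics within a fluency minute; word frequency, phonology or
orthography; cross-classified semantic/phonological cluster overlap;
by-item priming heterogeneity (the generator has no random slopes — which
is also why the selection tests legitimately expect slope terms to be
pruned); speed–accuracy trade-offs (correctness is independent of RT); and
fatigue or practice effects across trials.  Passing tests therefore certify
the *procedures* — filters, statistics, estimators, their calibration under
their own assumptions — not the realism of any simulated lexicon.

One illustrative consequence is built into the test suite: with items shared
across subjects, item noise does not average out over subjects, and a naive
by-subject paired t test is no longer exact — the classic
"language-as-fixed-effect" fallacy.  The generator's null-calibration
property is therefore checked with item variance set to zero, and the mixed
model (which handles crossed random effects) is checked at the full design.

## Numerical choices and problem sizes

* Determinism: every stochastic stage (generators, ER ensembles, Louvain,
  layouts) takes an explicit seed; identical seeds give byte-identical
  outputs, and pipeline outputs embed a hash of the analysis settings.
* Spanning-tree ties: lexicographic node-pair order.
* Exhaustive community search: restricted-growth-string enumeration,
  guarded at ≤ 10 nodes (Bell(10) = 115,975 partitions).
* Degenerate inputs have defined behaviour rather than NA surprises:
  edgeless graphs get the trivial partition with Q = 0; disconnected graphs
  reduce to the largest component (ASPL) or a spanning forest with a
  warning; zero ensemble SD marks a comparison degenerate.
* Simulation sizes used by the verification suite were chosen to make the
  Monte-Carlo error small relative to each assertion's tolerance while
  keeping the full suite runnable on a laptop: 200-graph brute-force oracle
  sweeps (5–10 nodes; exhaustive spanning-tree enumeration capped at
  choose(m, n−1) ≤ 20,000 subsets; exhaustive modularity at ≤ Bell(6)
  partitions per graph), a 1000-replicate ER(40, 0.5) calibration,
  50-replicate small-world discrimination at n = 100, and 150 recovery /
  200 null replicates of the full 40-subject × 40-item mixed-model
  pipeline.

## Known limitations

* Which clustering/path-length variants (weighted or not) underlie any
  given published table is often unstated; the package exposes modes and
  records them instead of asserting one true convention.
* Modularity-based community detection on correlation networks ignores
  negative edges; signed-network community methods are out of scope.
* The null model is ER with fixed p only; degree-preserving rewiring nulls
  are not implemented.
* Backward selection inherits the usual caveats of stepwise procedures:
  the selected structure is data-dependent, and reported p values do not
  account for the selection step.  The selection path is returned so the
  sensitivity can be inspected.
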