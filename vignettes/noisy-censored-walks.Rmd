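---
title: "Estimating individual semantic networks from fluency data with noisy censored random walks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating individual semantic networks from fluency data with noisy censored random walks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluencynet)
```

## The model

Semantic fluency data — ordered lists of category members produced by one
participant ("dog, cat, hamster, ...") — are modelled as the visible trace
of a random walk on that participant's semantic network $G$, an undirected,
unweighted graph over the unique items the participant produced. The walk
moves to a uniformly random neighbor at each step. An item is *emitted*
(written into the list) the first time its node is visited. Revisits are
normally *censored* (hidden), but with probability $p_{emit}$ per revisit
they are emitted anyway, producing a perseveration. $p_{emit} = 0$ recovers
the deterministic censored walk of repeat-free lists; clinically impaired
speakers show both shorter lists and more perseverations, which this single
parameter absorbs as a faulty self-monitoring rate.

The probability of a list factorizes into the stationary probability of its
first item, $\deg(i)/2|E|$, times one term per subsequent emission. Each
term is an absorption probability of a Markov chain: among the items already
emitted, censored moves follow $Q' = (1-p_{emit})\,Q$, where $Q$ is the
walk's transition matrix restricted to those items; the next emission is
reached through the fundamental matrix $E = (I - Q')^{-1}$ and the emitting
column of $R' = [\,p_{emit} Q,\ R\,]$ — a revisit column scaled by
$p_{emit}$, or an unscaled column for a first visit. Probability mass that
flows to items outside the list is deliberately lost: it corresponds to
producing a different list. When $I - Q'$ is singular the term is 0. Two
useful consequences fall out exactly: with $p_{emit}=0$ any list containing
a repeat has likelihood $-\infty$, and a list can never begin with an
immediately doubled item (the walk must first emit the intervening node).

Networks are estimated by maximum a posteriori search,

$$\hat G,\ \hat p_{emit} = \arg\max_{G,\,p}\; P(G)\,P(p)\,\prod_l P(X^l \mid G, p),$$

with a Bernoulli edge-wise prior anchored to a reference association
network (probability $2/3$ for pairs linked in the reference, $0.4$ for
reference pairs that are unlinked, $0.5$ when either item is unknown to the
reference — the fixed-prior reduction of a hierarchical edge model fitted
against free-association norms) and a uniform prior for $p_{emit}$ over the
grid $\{0.00, 0.01, \dots, 1.00\}$.

## The search

`estimate_network()` performs greedy stochastic ascent: toggle one node
pair, accept iff the log posterior strictly increases, and re-fit
$p_{emit}$ by a full 101-point grid search after every accepted toggle
(ties toward the smaller value). The search declares convergence after 300
consecutive non-improving proposals (`patience`, configurable). Design
choices where the procedure was genuinely open:

* **Initialization.** The search starts from the *naive network* linking
  every pair of items adjacent in any list. Every observed transition then
  has an edge, so the initial likelihood is finite whenever
  $p_{emit} > 0$ can explain the repeats.
* **Proposals.** With probability 0.5 a uniformly random pair drawn from
  pairs co-occurring within some list, otherwise a uniformly random node
  pair. Co-occurring pairs are where the data are informative; the uniform
  component keeps every graph reachable. Proposals that would disconnect a
  node used in the data are allowed and die naturally at $-\infty$
  likelihood.
* **Patience counts proposals,** not distinct pairs, and resets on every
  acceptance.
* **Numerics.** Absorption probabilities come from linear solves, never an
  explicit inverse; a solve failure or residual above $10^{-8}$ maps to
  probability 0 (the "fundamental matrix does not exist" branch).
  Accumulation is in log space and impossible data are an exact `-Inf`,
  not a sentinel. The grid prior constant $-\log 101$ is included so the
  stored log posterior is reproducible from its parts.
* One RNG (R's, shared with the compiled search loop) drives the whole
  estimation, so a seed makes results bit-identical.

The walker's position after a perseverated emission is the perseverated
node itself; every transition starts from the last *emitted* item. The
first item of a list is taken as never perseverated (cross-list repeats
are ordinary items: each list restarts the walk). The initial-item
probability uses degrees over the participant's full network even though
each list's chain is restricted to its own items.

## Mock ensembles and delta metrics

Networks estimated from more (or longer) lists have more nodes and edges,
which confounds raw group comparisons of size-sensitive measures. For each
participant, `mock_ensemble()` permutes the item order *within* each list
(list membership and lengths preserved), re-estimates a network with
identical settings, and repeats this 50 times by default. Every mock has
the same vocabulary as the participant, so `delta_measures()` —
participant value minus mock mean, per measure — isolates sequential
structure from data volume. Small-worldness is excluded (it is already a
ratio against size-matched random graphs), as is $p_{emit}$ (not inherently
size-correlated). A within-list permutation can place a repeated item at
positions 1–2, which no network can generate (see above); such replicates
are recorded as failed and excluded from the mock means rather than
retried, since redrawing would bias the ensemble's seeds. The failure count
is surfaced with a warning.

Network measures follow the standard definitions: density, mean/median
degree, diameter and average shortest-path length on the largest component
(`NA`, not 0, when undefined), and *global transitivity* — 3 × triangles /
connected triplets — rather than mean local clustering. The small-world
coefficient is $(C/C_{rand})/(L/L_{rand})$ against Erdős–Rényi $G(n, m)$
graphs matched on node *and edge count* (100 by default), the
largest-component convention applied to each.

## The synthetic cohort generator

No public corpus accompanies the clinical analyses, so `simulate_cohort()`
generates the study's *shape*: two groups walking on known networks, one
healthy-like, one impaired-like. The generator is also the package's test
oracle — the likelihood must reproduce its simulation frequencies.

The default base network is a connected Watts–Strogatz ring (15 nodes,
neighborhood 2, rewiring 0.05). A clustered small-world base is essential,
not cosmetic: healthy semantic networks are reported as strongly
small-world, and an Erdős–Rényi base (available as `base_type = "random"`)
has a small-world coefficient near 1 by construction, leaving nothing for
impairment to degrade. The impaired group differs in four ways, mirroring
the clinical contrast: 12 spurious edges added uniformly at random over
non-edges (per participant), a higher emission probability (0.30 vs 0.05),
and fewer, shorter lists (6 × 9 emissions vs 14 × 12). Lists terminate on
an emission *count* (the observable in time-limited fluency tasks), start
from the stationary distribution, and are fully reproducible from one
master seed that spawns per-participant seeds.

These sizes are a deliberately scaled-down emulation. At desk scale they
reproduce the qualitative clinical pattern — impaired groups yield denser,
less small-world estimated networks with higher fitted $p_{emit}$ and
delta metrics closer to their mocks — with clear margins across master
seeds. During design, conditions that violate the study's own description
failed informatively: an ER base produced no small-world contrast at all,
and much larger sparse worlds (25–40 nodes) flipped the density contrast
because the impaired group's data were too thin to recover its extra
edges. What passing these synthetic checks does **not** show: recovery of
clinical effect sizes, behavior on real transcripts (variant spellings,
category errors, cross-category intrusions), or robustness to the much
larger vocabularies of real semantic categories.

## Group statistics

`group_ttest()` gates a pooled vs Welch two-sample comparison on a
two-sided F test of variance equality at $\alpha = 0.05$ (the gate's level
is a package choice; the procedure reports which branch ran).
`fit_logistic()` is a plain binomial GLM, intercept plus main effects;
separation is detected from degenerate fitted probabilities and flagged,
not hidden. `stepwise_aic()` is bidirectional single-move AIC descent
(via `stats::step`), deterministic given the table. `split_half_cv()`
splits each class in half per repetition (preserving the class ratio),
fits on one half, predicts the other at threshold 0.5 (another undocumented
constant, chosen as the natural default), and averages the four confusion
counts over repetitions; repetitions whose training half loses a class are
skipped and counted. Participants contributing rows under both diagnoses
are kept as separate rows, matching the design this pipeline mirrors; the
resulting mild dependence between rows is a known caveat. No
multiple-testing correction is applied by default, matching the uncorrected
reporting convention of the analyses this package reproduces. Stepwise
*selection* is performed once on the full table; cross-validation refits
only the selected model's coefficients per split.

## Worked example

```{r example, eval = FALSE}
set.seed(1)
sim <- simulate_cohort(cohort_spec(), seed = 1)
cp <- sim$corpora[["A01"]]
fit <- estimate_network(cp, seed = 1)
fit
compute_measures(fit$network)
ens <- mock_ensemble(cp, k = 50, seed = 2)
delta_measures(compute_measures(fit$network), ens)
```

## Problem sizes used by the automated checks

The test suite and `scripts/acceptance.R` run everything at reduced but
honest scales, chosen as the package's own benchmark sizes: the
Monte-Carlo likelihood oracle uses $10^5$ three-emission walks per
condition (and $10^6$ for the single path-graph closed form), exhaustive
MAP enumeration covers vocabularies of 3–4 nodes, edge-recovery benchmarks
use 15-node networks with 5 vs 40 lists over 5–10 seeds, and the synthetic
cohort uses 10 participants per group with 8 mock replicates per
participant (the analysis default remains 50).

## Known limitations

* Real transcripts need upstream cleaning (plural/singular merging,
  compound variants); normalization here is deliberately limited to
  case/whitespace so that it is deterministic and reversible.
* A real list that *begins* with an immediate repeat ("cat, cat, ...") has
  zero likelihood under every network; estimation fails loudly on such
  input rather than silently dropping data.
* The MAP search is greedy ascent, not annealing or sampling; on
  multimodal posteriors it can stick, which the exhaustive-oracle test
  quantifies (it demands ≥ 90% success over seeded runs on tiny
  vocabularies).
* Weighted, directed, or jump/teleport walk kernels are out of scope.
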