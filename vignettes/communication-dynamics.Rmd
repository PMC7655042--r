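---
title: "Collision-limited communication dynamics on mesoscale brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collision-limited communication dynamics on mesoscale brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcollide)
```

## The model

`netcollide` simulates communication on a directed brain network as a
population of synchronous message-passing agents. Time is discrete. At every
step, each node inspects its incoming messages: deliveries emitted by its
in-neighbours on the previous step plus any of the L fresh messages injected
this step at uniformly chosen nodes (with replacement, so two injections can
land on one node and collide). Collisions are resolved nonlinearly:

* **destroy-all** (the default): a node passes a message only when *exactly
  one* arrives; two or more coincident messages annihilate and the node
  stays silent. This is the fully punitive reading of signal collision.
* **let-one-pass**: one survivor of any collision is routed onward, the rest
  are deleted. This milder rule is provided for contrast; under information
  spreading it drives the network into near-saturation (the acceptance
  checks compute the ratio, which exceeds 2x the destroy-all level at 5%
  load on the bundled fixture).

A firing node routes per the configured model:

* **IS** (information spreading): a copy on *every* outgoing edge —
  redundancy as a strategy against destructive collisions;
* **RW** (random walk): one copy on *one* uniformly chosen outgoing edge —
  the conservative diffusion end of the routing spectrum.

All emissions land simultaneously at the next step; there are no buffers,
no message identities, and no asynchronous updates. A firing node with no
outgoing edges absorbs its message. Edge weights play no role in routing
(an edge exists iff its weight is positive): the simulated networks are
binary, and weights matter only for pre-filtering (see thresholding below).

On graphs where every out-degree is one the two models coincide; the
implementation routes degree-1 nodes without consuming randomness, so IS
and RW traces are bit-identical there — a useful engine check.

## Measurements

Per trial we record, for each node and step, the *attempted* activity (the
incoming-message count before collision resolution) and the binary *net*
activity (whether the node actually passed a message). Summaries:

* mean fraction of net-active (or attempted-active) nodes per step;
* **Treves–Rolls sparseness** of windowed activity counts,
  \(S = (\bar{x})^2 / \overline{x^2}\): squared mean over mean square of the
  per-unit activity counts \(x_n\). S runs from \(1/N\) (one active unit —
  maximal sparseness) to 1 (uniform activity), and is scale- and
  permutation-invariant. Reference values the test-suite recomputes by
  sampling: half-normal magnitudes give \(2/\pi \approx 0.64\), exponential
  0.5, generalized Pareto with shape 0.25 gives 1/3.

*Population* sparseness applies S across nodes within a time window;
*lifetime* sparseness applies it across windows for each node. Windows are
consecutive, non-overlapping, aligned to the first post-burn-in step, with
any trailing partial window dropped. A window (or node) with no activity at
all has undefined sparseness (0/0); such cases are excluded from averages
and reported as a count rather than coerced to either pole, since coercing
to 0 or 1 would bias the average toward maximal or minimal sparseness.
Aggregation order is: S per window (or node), arithmetic mean within trial,
then mean across trials.

## Defaults and what they mean

| parameter | default | meaning |
|---|---|---|
| `n_steps` | 1000 | steps per trial |
| `burn_in` | 500 | steps discarded before measuring equilibrium dynamics |
| `n_trials` | 500 | independent trials per condition |
| `window` | 5 | sparseness window length (steps) |
| load | 1 message – 50% of N | injection per step; the supported regime |
| swaps | 10 × edges | accepted Maslov–Sneppen swaps per randomization |

Loads can be absolute (`load_messages(1)`) or a percentage of network size
(`load_percent(10)`); a percentage resolves to `round(p/100 * N)` with
halves away from zero, floored at one message. Loads above 50% of N are
rejected — beyond that regime collisions dominate so completely that the
dynamics are uninformative. Longer windows shift the absolute S value
(longer windows average activity toward uniformity), but the model ordering
is insensitive to the choice; the suite verifies this for windows 5 and 10.

The default trial counts keep a full condition (500 × 1000 steps) tractable
on a laptop; the test-suite and the worked examples use scaled-down
configurations (typically 20–50 trials of 300 steps with burn-in 150,
networks of 25–100 nodes) chosen so that every qualitative contrast they
assert is far outside trial-to-trial noise at that size.

## Connectome handling

Readers accept delimiter-sniffed CSV/TSV weight matrices (optional label
row/column; a `transpose` flag for matrices stored target-major, since
tracer matrices circulate in both conventions) and source/target/weight
edge lists (duplicate rows sum). Structural filters:

* `threshold_edges(g, w_min)` drops edges *strictly below* the threshold —
  a weight exactly at the threshold is kept. Used to thin dense
  tracer-weighted networks (e.g. dropping weights below 0.0136, near the
  modal tracer weight) so that degree-preserving randomization has room to
  move.
* `strip_self_loops(g)` zeroes the diagonal; self-loops are otherwise legal
  and a looped IS copy re-arrives at its own node the next step and
  participates in collisions there.
* `restrict_to_active_core(g)` removes sources and sinks. It is single-pass
  by default (matching a one-shot filter by reported degree); the removal
  can expose new sources/sinks, so an `iterate` flag runs it to a fixpoint.
  The two variants are both available because published node counts for
  filtered connectomes do not always say which was used. The fixpoint of a
  chain is the empty graph, so the graph container permits zero nodes;
  simulation entry points require at least one.

Internally node indices are integers in matrix order; user-facing labels
are preserved verbatim.

## Null models

`maslov_sneppen_randomize` conserves every node's in- and out-degree by
target swaps of ordered edge pairs, rejecting any swap that would duplicate
an edge or (by default) create a self-loop; existing self-loops stay in
place and outside the swappable pool, which conserves both degree vectors
without manufacturing loops. Outputs are binarized to weight 1, matching
the simulator's use of edges. The default of 10 × |E| accepted swaps is
the usual mixing convention. Some graphs are locked under this move set —
in a directed 3-cycle every candidate swap would create a self-loop — so
after 200 × the requested swaps of failed attempts the routine warns with
diagnostics and returns the graph reached so far instead of spinning
forever; for a locked graph that is the input itself, which the test-suite
proves by exhaustive enumeration of candidate swaps.

In ensemble comparisons (`randomized_ensemble_comparison`) every trial of
the randomized arm simulates a *fresh* randomization, so the empirical
network is compared against a family of nulls rather than one draw;
edge-set hash collisions between draws are counted and reported. Per load,
mean net activity and population sparseness are compared with two-sided
Welch t tests. Welch rather than pooled-variance because the two arms'
variances visibly differ across routing models; one observation per trial;
no multiple-testing correction across loads (comparisons are reported
per-load, and readers can apply their own correction). Percent differences
are relative to the randomized arm.

`directed_erdos_renyi` supplies the matched-size, degree-free control; it
delegates uniform G(n, m) sampling to igraph.

## The synthetic fixture generator

`connectome_like_fixture(n, density, self_loop_rate, seed, sigma)` places
exactly `floor(density * n * (n-1))` distinct non-self edges by weighted
sampling without replacement over all candidate slots, with slot
probability proportional to the product of lognormal out- and in-propensities
(log-sd `sigma`, default 1). This yields heavy-tailed degree sequences with
an exact edge count and no rejection loops; self-loops are added on
distinct random nodes. At 213 nodes and density 0.375 the fixture matches
the scale of the largest mesoscale connectome commonly analyzed
(about 17,000 edges).

What the fixture does **not** emulate: the empirical connectomes'
core–periphery and hub architecture, their reciprocity, and their spatial
wiring. Consequences that matter for interpreting the tests:

* The bimodal attempted-count distribution under IS (a dominant zero peak
  plus a secondary mode from high-in-degree nodes) requires hub structure;
  the suite checks it on a hub-enriched fixture in which a few nodes
  receive projections from nearly everywhere.
* The load at which the IS/RW activity ordering crosses over depends on
  the depth of the IS collision plateau, which is topology-dependent. On
  the bundled 100-node, 20%-density fixture the suite's sweep places the
  crossover between 5% and 10% load: RW activity grows strictly and
  roughly fourfold across loads while IS stays within 1.5× of its minimum,
  RW is less active and sparser at the minimum load of one message per
  step, and IS is less active and sparser from 10% load upward — but at
  exactly 5% IS still sits slightly above RW on this fixture family
  (heavier-tailed variants move the crossover up, not down, because
  walkers pile onto hubs and collide). Passing the qualitative suite
  therefore demonstrates the routing-model signatures, not the empirical
  crossover position, which requires the real connectomes.

## Reproducibility

Every trial's RNG stream is derived from (master seed, trial index,
condition hash) via multiplicative mixing mod \(2^{31}-1\): trials are
independent of how many other trials ran, different conditions and arms
under one master seed draw independent randomness, and a full sweep table
is a pure function of (network, configuration, seed). Functions that accept
a `seed` argument restore the caller's RNG state on exit.

## Limitations

Messages carry no identity, so delivery rates and latencies are out of
reach by design; there is no buffering, queueing, or partial-redundancy
routing between the IS and RW extremes; collision rules are uniform over
nodes and time. Statistical comparisons assume independent trials, which
the seeding scheme guarantees, but make no small-sample corrections beyond
Welch degrees of freedom.
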