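---
title: "Methods: recovering relational maps from adaptation and response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: recovering relational maps from adaptation and response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relmap)
```

This vignette documents the models implemented in `relmap`, the assumptions
behind them, the tunable parameters and their defaults, what the synthetic
cohorts do and do not emulate, and the numerical decisions taken where the
design was genuinely open.

## The measurement model

The package analyses *per-transition responses*: one scalar per subject per
ordered pair of distinct objects (i → j). In the neural setting this is the
adaptation (repetition-suppression) parameter estimate for object j when
preceded by object i; in the behavioural setting it is the demeaned
log response time under the same conditioning. Both are assumed to scale
with the representational distance between i and j, so all proximity
regressors are oriented to *increase* with distance: link and Euclidean
distances directly, communicability as the negative matrix exponential
`−e^A`, and the successor representation through its negative.

On a graph with adjacency matrix `A`:

* `link_distance_matrix()` — minimum edge count between nodes.
* `euclidean_distance_matrix()` — layout distances; the default layout puts
  every linked pair at distance exactly 1, the idealised planar embedding.
* `communicability_matrix()` — `−e^A`, a factorially discounted sum over
  walks of every length. No free parameter.
* `successor_representation_matrix()` — `(I − γA)^{-1}`. The geometric
  series converges only for `γ λ_max < 1`, so the discount is specified as
  `gamma_fraction` of the critical value: `γ = gamma_fraction / λ_max`,
  default 0.85. Values ≥ 1 are rejected as divergent. (Quoting the discount
  relative to `λ_max` is the only reading under which the conventional
  "0.85" produces a convergent series on graphs whose spectral radius
  exceeds 1, as any multi-edge graph has.)
* `empirical_edge_lengths()` + `directed_shortest_paths()` — experienced
  transition counts `c` on each directed link become lengths
  `d = 1 − c/(1 + c_max)`; pair distances are directed shortest paths, and
  the symmetrised variant (mean of the two directions) is the
  non-directional distance a true map would use. The companion
  `asymmetry_index()` is `|xy − yx|/(xy + yx)`.

## Default graphs are reconstructions

The true 7-node test graph and 12-node training graph are published only as
figures. The defaults shipped here are *constraint-satisfying
reconstructions*, not the original structures: `default_reduced_graph()`
was selected among the seven-edge topologies
that contain every link named in the text (1–2, 1–5, 3–5, 4–6, 5–7), omit
every named non-link (2–4, 4–7, 1–7), are connected and have diameter
exactly 3. It is a 5-cycle (1–4–6–7–5) with pendant nodes 2 and 3, drawn on
a unit-side pentagon with pendants one unit outward, so all linked pairs
are at Euclidean distance 1 and the drawing has no crossings.
`default_training_graph()` embeds it as an induced subgraph among 12 nodes
with minimum degree 3 (so constrained walks rarely stall). Every analysis
is topology-parametric — supply your own graph as JSON to replace the
defaults.

## Sequence designs

Three generators reproduce the experiment's designs, with the design counts
guaranteed *by construction* rather than by rejection sampling:

* `generate_training_walk()` — a random walk on the training graph in which
  consecutive items are always linked and an item may not reappear until at
  least `exclusion_window = 3` other items intervened. Dead ends under the
  window are handled by bounded backtracking (budget 50 steps), then by a
  deterministic seed-offset restart, so output is reproducible given the
  seed. Default length 133 items per block.
* `generate_scanner_run()` / `generate_behaviour_block()` — transition-
  balanced sequences built as randomised Eulerian circuits (Hierholzer's
  algorithm) on the complete directed multigraph with arc multiplicity
  `reps_per_transition`. Every ordered pair of distinct objects therefore
  occurs *exactly* `reps` times and objects never repeat; lengths are
  `n(n−1)·reps + 1` (421 for 7 objects × 10 reps; 127 for 7 × 3). A
  rejection sampler could not guarantee termination, which is why the
  circuit construction was chosen.
* `annotate_cover_task()` — patch flags drawn Bernoulli(0.5) per trial and
  exactly one probe per ordered transition (42 probes = 10% of the 420
  transition trials), with the probe trial and the two following trials
  marked excluded, mirroring the button-press exclusion rule.

`mean_gap_matrix()` implements the temporal-proximity regressor: for each
ordered pair, the mean number of items between an occurrence of the second
object and the *nearest prior* occurrence of the first. "Average time
between two objects" is ambiguous (nearest prior vs all occurrence pairs);
nearest-prior was chosen because the regressor is meant to capture the
temporal contiguity that could mimic a distance effect, and averaged over
both directions by default since it is used as a symmetric regressor.

Events can be exported as BIDS-style TSV with onsets synthesised from the
stated timing model (1 s or 2 s stimulus, truncated-Poisson ITI with mean
2 s). The truncation bounds are unstated in the source; the defaults are
1–5 s, exposed as arguments.

## Synthetic cohorts

The generative model is the minimal structure the analysis chain
presupposes:

```
response(s, i → j) = β · m(i, j) + u_s(j) + ε,
u_s(j) ~ N(0, object_effect_sd²),  ε ~ N(0, noise_sd²)
```

with `m` one of the proximity metrics. Per-object offsets exist because the
object-demeaning control only makes sense if object main effects are real;
Gaussian trial noise is the weakest assumption compatible with OLS and
t-based group inference. Response times use the same structure on the log
scale: `log RT = rt_baseline + u_s(j) + β·m(i,j) + ε`, exported in
milliseconds.

Defaults for the adaptation cohort are `n_subjects = 23`, `β = 1`,
`object_effect_sd = 0.5`, `noise_sd = 1` (signal-to-noise of order 1, in
arbitrary units — the published units are arbitrary too). For response
times the test suite uses `noise_sd = 0.2` log-units (≈ 20% trial-to-trial
RT variability, typical of speeded categorisation), `object_effect_sd =
0.05`, and a metric slope of `0.02` log-units per communicability unit,
sized so the group-level communicability effect lands near the magnitude
reported for the real cohort (group t ≈ 3 at n = 26); a smaller slope
produces an underpowered design because object demeaning and the strong
collinearity between communicability and link distance inflate the
coefficient standard error.

What the simulator deliberately does **not** emulate: haemodynamics, voxel
noise, physiological confounds, learning dynamics across training blocks,
or any nonlinearity between distance and response. Passing tests therefore
show that the *analysis chain* is correct and well-calibrated under its own
assumptions — not that real BOLD or RT data satisfy those assumptions.

## Analysis chain

`transition_regression()` fits, per subject, OLS with intercept over the
n(n−1) transition responses, with the proximity metrics competing for
variance; regressors are mean-centred by default (scaling optional —
whether the original analysis z-scored regressors is unstated, and slopes
are easier to interpret unscaled). Group inference is a two-tailed
one-sample t-test on each coefficient across subjects — the quantity a
"paired t-test on regression coefficients" reduces to when a single
coefficient is tested against zero. Zero across-subject variance is
flagged (`NA` statistics with a warning) rather than treated as an error.
Rank-deficient designs fail with the collinear columns named.

`distance_contrasts()` is the model-free version: per-subject means by link
distance (1, 2, 3), paired t-tests for connected vs non-connected and for
distance 2 vs 3, and a one-way repeated-measures ANOVA across the three
bins (fitted via `stats::aov` with a subject error stratum; `F = 0` by
convention when the between-bin sum of squares vanishes, which covers the
all-equal degenerate case where the F ratio is otherwise 0/0). Optional
per-object demeaning reproduces the control for object main effects.

`preprocess_rt()` implements the behavioural chain: log-transform →
per-subject per-object demeaning (across all blocks; demeaning per block
would also be defensible but couples estimates to block-level noise) →
per-transition-per-block means → across-block means. Incorrect trials are
excluded by default (switchable); a transition absent from any block is an
error naming the pair and block. Note one exact consequence of demeaning:
noiseless data preprocess to `β·m(i,j)` *minus a per-object constant* (the
object's mean metric value), not to `β·m` itself; the tests assert exactly
this structure, and it is also why a small systematic bias can appear on
competing regressors when the generative slope is large relative to noise.

`communicability_bins()` sorts the 42 ordered transitions by
communicability and splits them into `n_bins` equal-count bins (default 6,
matching the figure this summary is read from; the accompanying text says
seven — the discrepancy is in the source, and the bin count is an
argument). Communicability is symmetric, so the two orientations of each
pair are exactly tied; ties at bin boundaries are broken by the stable
enumeration order of ordered pairs. A non-divisible pair count spreads the
remainder over the leading bins.

## Map recovery

`group_transition_matrix()` averages responses across subjects (diagonal
fixed at 0, since objects never repeat). `prepare_dissimilarity()`
symmetrises by averaging the two triangles and shifts so the off-diagonal
minimum is exactly 1, re-zeroing the diagonal. (The original description
subtracts the matrix minimum *before* symmetrising; the two orders differ
only by an additive constant, which cannot affect nonmetric MDS, metric
MDS up to scale, or any correlation used here — the order implemented pins
the off-diagonal minimum at exactly 1.)

`mds_embed()` defaults to nonmetric (Kruskal stress-1) scaling via
`MASS::isoMDS` with 20 restarts — the classical solution plus 19 random
Gaussian initialisations — keeping the lowest-stress solution,
deterministically given the seed. The named tool in the original analysis
defaults to a nonmetric criterion, but the choice is not stated, so
`method = "metric"` (classical scaling) is available. One consequence worth
knowing: nonmetric scaling preserves *rank order only*, and a link-distance
matrix contains heavy ties (only values 1, 2, 3), so even a rank-perfect
embedding (stress ≈ 0) of exact link distances yields a Pearson correlation
with those distances of about 0.92, not 1; metric scaling of the same
matrix exceeds 0.99. The permutation test is unaffected, because observed
and null statistics use the same embedding.

`enumerate_null_graphs()` builds the topology null exhaustively: all edge
subsets of the required size, filtered to connected graphs ("complete" in
the original description, glossed there as every node reachable from every
other — i.e. connected). For 7 nodes and 7 edges that is 68,295 of the
C(21,7) = 116,280 candidates. Enumeration and the per-member link-distance
and crossing computations are vectorised across the whole ensemble (batched
boolean matrix products; crossings as a quadratic form over a precomputed
21 × 21 edge-pair crossing table), which keeps enumerating and scoring the
full null well inside a minute on one CPU. Enumeration refuses candidate
spaces above 5 × 10⁶ subsets.

`map_recovery_test()` computes the Pearson correlation (Spearman optional)
between embedded distances and true link distances over the 21 unordered
pairs, and the permutation p as the fraction of null members whose
link-distance correlation is ≥ the observed one — no +1 smoothing, and the
true graph is itself a member of its null, so p is never exactly 0. The
crossing test counts unordered edge pairs whose *open* segments properly
intersect at the fixed embedding: pairs sharing an endpoint never count,
T-junctions (an endpoint interior to another segment) do not count, and
collinear overlap of positive length counts as one crossing (it is an
unambiguous planarity violation).

## Determinism and problem sizes

Every randomised operation takes a seed; internally, stage seeds derive
from the run seed plus the stage name via a 32-bit FNV-1a hash
(`derive_seed()`), so stages can be re-run in isolation and whole pipelines
are byte-reproducible. Test-suite problem sizes are the published design
sizes where those are the point (421/127/133-item sequences, the full
68,295-graph null, 23- and 26-subject cohorts) and small otherwise; the
complete suite runs in well under a minute.

## Known limitations

* The default graphs match every textual constraint but are not guaranteed
  to be the original figures' graphs; conclusions about the *method* do not
  depend on this, but numeric values computed on the defaults (e.g. the
  fraction of crossing-free null topologies at a given embedding) will
  differ from the originals.
* Whether the original Euclidean regressor used figure coordinates or an
  idealised unit-edge embedding is unstated; the default layout implements
  the idealised reading (all linked pairs at distance 1).
* The voxel-level pipeline (HRF convolution, GLM estimation, multiple-
  comparison correction) is out of scope; the package starts from
  per-transition response estimates.
* Group inference assumes approximately Gaussian coefficient distributions
  across subjects; with very few subjects the t-based p-values are
  nominal.
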