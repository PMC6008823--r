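---
title: "Recommending next-step clinical activities from treatment trajectories"
author: "dtprec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recommending next-step clinical activities from treatment trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dtprec)
```

## The process model

`dtprec` treats a patient's hospital episode as a *discrete controlled
process with memory*. One step is one inpatient day. The state at step $t$
is a vector $V_t = (U_t, X_t)$:

* $U_t$, the **control block**, holds one non-negative number per activity
  in the glossary (drugs, diagnostic tests, lab tests, procedures). Each
  component is *integral* — the full dose of that drug, the running count of
  that test, accumulated from admission through step $t$. A zero means the
  activity has never been applied; because the quantities are cumulative,
  $U$ is component-wise non-decreasing along a process.
* $X_t$, the **monitored block**, holds observed patient properties
  (inpatient days, temperature, lab markers, ...). Components may be missing
  at any step; categorical properties are digitized to 1-based level indices
  in glossary order at ingest.

The action a doctor took between two consecutive states is the control
delta $\Delta U_t = U_{t+1} - U_t \ge 0$; its support (`applied_set()`,
default tolerance 0: any positive increment counts) is the set of
prescribed activities. A *process bank* is an ensemble of such processes
sharing one glossary and one nosology code; it is the raw material all
three engines are taught from. Recommendation is the inverse problem: given
a current state, predict $\Delta U$.

## State embedding and metric

All engines operate in a common embedded space. `fit_normalizer()` computes
per-component means and *population* standard deviations over all states of
the teaching bank (controls and monitored components uniformly, missing
values excluded from the moments). `embed_state()` mean-imputes missing
monitored values, z-scores every component, and maps zero-variance
components to 0 — they carry no information, and excluding them from the
metric keeps distances finite without an arbitrary weighting. A standard
deviation floor of $10^{-9}$ guards the division for near-constant
components. The distance $d(x, y)$ is the Euclidean norm of the difference
of embedded vectors.

Two choices here were genuinely open. First, whether the metric should
compare full states or only monitored properties: the query to the
recommender is the patient's current state *including* the accumulated
controls, and the treatment history is exactly what makes the process a
process-with-memory, so the default embeds the full vector; `which =
"monitored"` restricts the metric for sensitivity studies. Second, missing
values: mean imputation is the simplest defensible convention — after
z-scoring an imputed component sits at 0 and is neutral in the metric.

## The case-based engine

`case_graph()` realizes precedent-based recommendation as a navigable
graph. Every state of every teaching process is a node; each node is linked
to its $n$ nearest nodes under $d$ (default $n = 8$), with lists sorted
ascending and ties broken by lower node id; within-process sequence links
connect step $t$ to step $t+1$. Construction is exact brute force — at the
package's intended desk scale ($10^2$–$10^4$ nodes) this is cheap, and it
makes the neighbour structure reproducible to the bit.

`greedy_search()` answers a query by random-restart greedy descent: from
each start node move to the neighbour strictly closest to the query (ties
to the lower id) until no neighbour improves, then keep the best terminus
over all restarts. Distances to the query are memoized, so with restarts
equal to the node count the search degenerates gracefully into exhaustive
nearest-neighbour — that equivalence is the oracle the test suite checks.
Defaults follow the sizes that work at scale: half a percent of the node
count (at least 5) for a global search, and 10 starts when the search is
restricted to a *layer* — the sub-population of nodes at the query's own
step index. Layering assumes the query knows its own day, which holds in
the recommendation loop, and is markedly more reliable on protocol-driven
banks, where same-day states cluster tightly and cross-day jumps create
local minima for the global search.

The recommendation is the precedent's own next action: if the nearest node
$t$ has a successor, recommend $\Delta U = U_{t+1} - U_t$ and annotate it
with the precedent process and step. When the nearest node is a terminal
state, the engine falls back to the best non-terminal restart terminus; if
no restart found one, it reports an explicit no-recommendation outcome.
This fallback is the package's own convention — a terminal precedent simply
has no observed next step to offer.

Teaching is incremental: `add_process()` embeds the $k$ new states, computes
their neighbour lists against the $m$ pre-existing nodes only (exactly
$k \cdot m$ metric evaluations, tracked by the graph's counter), and adds
$k$ nodes, $k - 1$ sequence links and $k \cdot n$ neighbour edges. Existing
nodes' lists are *not* refreshed — that keeps the teaching cost at
$k \cdot m$ and the accounting exact; `refresh_neighbors()` is the
compensating full rebuild for occasional maintenance. The new process is
retrievable immediately, which is the case-based approach's defining
advantage over the taught networks below.

## The single-layer network

`slnn()` trains one output neuron per control on all non-terminal teaching
states. The input is the embedded state plus a bias component fixed at 1;
neuron $j$ computes $a_j = w_j \cdot x$ and the Gaussian bell activation
$y_j = \exp(-a_j^2 / 2)$. The bell shape encodes a clinical fact about
integral controls: regulatory standards and insurance limits cap cumulative
doses, so the propensity to prescribe peaks in a region of state space and
decays beyond it, unlike a monotone sigmoid. Centre and width of the bell
are conventions (0 and 1); the weights absorb any affine repositioning.

Targets are the binary next-step application indicators pushed into the
open interval: $1 - \varepsilon$ where the control was applied, else
$\varepsilon$ (default $\varepsilon = 0.01$). Interior targets keep the
quadratic residual
$E(W) = \sum_{\text{states}} \sum_j (y_j - t_j)^2$
meaningful for an activation that never reaches 0 or 1 exactly. The
gradient is computed in closed form,
$\partial E / \partial w_{jk} = \sum 2 (y_j - t_j)(-a_j)\, y_j\, x_k$,
and minimized by full-batch steepest descent with Armijo backtracking
(halving, slope constant $10^{-4}$, accepted step doubled as the next trial
step). The loss trace over accepted steps is non-increasing by
construction, and the explicit gradient is verified against central finite
differences in the tests.

One numerical pitfall shaped the initialization: the all-zero weight matrix
is a *stationary point* of this objective — $\partial y / \partial a = -a y$
vanishes at $a = 0$ — so descent started at zero never moves. The default
initialization therefore sets the bias weights to 0.5 and everything else
to 0: deterministic, symmetric across outputs, and off the critical point.
A seeded random initialization is available. Prediction thresholds the
activations at $\theta$ (default 0.1, boundary inclusive); recommendation
counts are monotone non-increasing in $\theta$, which gives the ROC sweep
its shape.

## The probabilistic neural network

`pnn()` is a Parzen-window Bayes classifier. Every non-terminal teaching
state is a kernel centre; the single kernel shape shared by all states is a
multivariate Gaussian with diagonal covariance $\sigma^2 \mathrm{diag}(s^2)$,
where $s$ holds the per-component teaching standard deviations (floored at
$10^{-6}$) and $\sigma$ is the width multiplier. For each control $L$ the
centres split into class $K_{L1}$ (states where $L$ was applied next) and
$K_{L0}$ — $2m$ classes for $m$ controls. Class densities are the means of
their kernels; `pnn_posterior()` applies Bayes' formula with empirical class
priors,
$p(K_{L1} \mid q) = \pi_1 f_1(q) \, / \, (\pi_1 f_1(q) + \pi_0 f_0(q))$,
recommending $L$ when the posterior reaches the threshold (default 0.5, a
package convention). Degenerate classes are explicit: empty $K_{L1}$ gives
posterior 0, empty $K_{L0}$ gives 1.

All kernel arithmetic is done in log space with a max-shift
(log-sum-exp): state vectors here have hundreds of components, and a direct
product of that many Gaussian factors underflows double precision long
before the posterior itself becomes extreme. The tests confirm the
log-space path agrees with direct density arithmetic to $10^{-12}$ on
low-dimensional instances, and that as $\sigma \to \infty$ posteriors
collapse to the class priors.

`select_sigma()` picks the width on a held-out validation split
(process-level, default 20%) by balanced accuracy over all (state, control)
decisions, with ties to the smaller width; the packaged grid is
$\{0.1, 0.5, 1, 2.5\}$. Balanced accuracy is used because applied controls
are rare: raw accuracy would reward the all-negative predictor. On noisy
banks wide kernels win — sharp kernels ($\sigma = 0.1$) reduce to
one-nearest-kernel behaviour and inherit every omission and spurious
prescription in the teaching data, while wide kernels average them out.

Terminal states are excluded from kernels and from network training
throughout: they have no observed next action, hence no class membership
and no target. Empirical class frequencies serve as priors (rather than
uniform ones) so that never-applied controls are never recommended.

## The synthetic clinic

Real hospital-record banks cannot be shipped, so `generate_bank()` produces
protocol-driven synthetic ones. Each process draws a latent severity
$\sim \mathrm{Uniform}(0,1)$; a length of stay from
$\text{base} + \mathrm{round}(\text{severity} \times \text{scale})$ plus a
small integer jitter (floored at 2 days); and then plays out the template's
protocol rules day by day. A rule prescribes a fixed daily amount of one
control over a day window, optionally gated on a severity interval, and
fires with probability $\text{adherence} \times (1 - p_{\text{omit}})$.
Noise is layered on top: omission ($p_{\text{omit}}$), spurious
prescriptions (one unit of a uniformly random control per affected step),
log-normal multiplicative dose jitter, and missingness of monitored
observations. Monitored recovery markers follow
$\text{baseline} + \text{effect} \times \text{severity} \times e^{-\text{rate}\, t}$
with Gaussian observation noise, so severity — which selects the protocol
branch — leaks into the monitored block. That leak is deliberate: it is
what makes neighbours in embedded state space share protocol branches, and
hence what makes case-based recovery a meaningful test rather than a
coin flip.

The packaged `default_template("pneumonia_like")` models an inpatient
pneumonia-style episode: 60 controls (30 drugs, 20 lab tests, 10
procedures), an inpatient-day counter plus temperature and CRP recovery
markers, a common backbone (daily antibiotics, admission work-up, periodic
monitoring), and three severity-gated branches (mild/moderate/severe) with
a mean length of stay near ten days. All template rules use adherence 1, so
with the noise block off the generator is fully protocol-deterministic and
the per-step applied set equals the template schedule exactly — the exact
recovery oracle the tests rely on. One master seed drives a bank;
per-process sub-seeds are drawn up front, making generation
order-independent and serialized banks byte-identical across runs.

What the generator does *not* emulate: pharmacokinetics, comorbidity,
dose tapering, inter-hospital practice variation, or any calibration to a
real nosology's statistics. Passing tests on these banks demonstrate that
the engines recover structure that is present and robustly survive the
modelled noise; they say nothing about accuracy on real records, where the
signal-to-noise profile is unknown.

## Evaluation accounting

`evaluate_binary()` scores one decision per (state, control) pair over all
non-terminal states of the control precedents. The headline shares follow
the recommendation-centric convention: the *positive share* is the fraction
of issued positive recommendations that match the doctor's actual action
(precision over positives), and the *negative share* is its analogue over
negatives — deliberately not sensitivity/specificity. `evaluate_case()`
scores the case engine per actually-applied activity: *correct* if the
recommended applied set contains it, *unable* otherwise (including explicit
no-recommendation outcomes), and among correct ones *different control
level* when the recommended amount differs by more than 10% relative (with
a one-unit absolute floor — the package's rule; any published analogue
leaves it unspecified). The identities correct + unable = total and
different_level ≤ correct hold by construction. `roc_curve()` sweeps a
threshold over scores with inclusive boundaries, giving endpoints (1,1)
and (0,0) and coordinates monotone in the threshold.

## Problem sizes and determinism

The test suite and the acceptance script run at desk scale, chosen so the
full pipeline exercises every code path in seconds: banks of 10–110
processes (up to ~1,100 graph nodes) for the case engine, 500-node graphs
for the search-oracle equivalence, 30–60-process noisy banks for the
networks, and a few hundred descent steps for the loss-monotonicity check.
Every stochastic step — generation, splits, restarts, random
initializations — flows through explicit integer seeds, so all results in
the README and the acceptance output are exactly reproducible.

## Known limitations

* Monitored properties are single-valued per step; repeated within-day
  measurements must be aggregated upstream.
* The case graph's neighbour lists are directed exact k-NN; no
  approximate-NN index is provided, so construction is quadratic in the
  node count.
* Mean imputation is neutral but crude; informative missingness is not
  modelled.
* The engines share one glossary per bank; multi-nosology banks and
  comorbidity code hierarchies are out of scope.
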