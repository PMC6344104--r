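---
title: "Modeling ecosystem dynamics with conditional linear Gaussian DBNs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling ecosystem dynamics with conditional linear Gaussian DBNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecodbn)
```

## The modeling problem

Annual ecosystem monitoring programs produce short multivariate time
series: a few dozen years of climate indices, physiochemical measurements
(nutrient loads, bottom-water dissolved oxygen), primary production,
zooplankton biovolume, seabird abundance, and stock-assessment recruitment
deviations for commercially important species. Two features make these
series awkward for standard multivariate autoregressions. First, the
system is not stationary: basin-scale climate modes switch between
persistent warm and cool phases that change the relationships among the
observed components. Second, with ~30 observations and ~30 variables, an
unconstrained model is hopeless; predictive structure has to be sparse and
found by search.

`ecodbn` addresses both with a two-slice dynamic Bayesian network whose
observed nodes are conditional linear Gaussian (CLG) and whose regime
switching is carried by binary hidden Markov chains. Each observed scalar
node $Y$ with continuous parents $X$ and discrete (hidden) parents $Q$
follows

$$ Y \mid X = x, Q = i \;\sim\; \mathcal N\!\big(\mu_i + W_i\,x,\ \sigma^2_i\big), $$

so a hidden state switches the intercept, the regression weights and the
noise variance of its children. Hidden nodes are binary first-order Markov
chains (initial distribution $\pi$, transition matrix $A$). All data enter
standardized to mean 0, standard deviation 1 per series (sample moments,
$n-1$ denominator), which puts every variable on a comparable scale and is
undone only when physical units matter (the temperature press).

### Edge conventions

Edges are either intra-slice (within a year) or inter-slice (lag 1).
The package commits to one reading, applied everywhere:

* hidden $\to$ observed edges are intra-slice ($H^t \to X^t$): the
  current regime shapes the current year;
* all learned observed $\to$ observed dependencies are realized at lag 1
  ($X^{t-1} \to Y^t$), because prediction only ever conditions on the
  previous year's evidence;
* hidden $\to$ hidden edges exist only as each chain's own lag-1 link.

With all cross edges at lag 1, the unrolled network is automatically
acyclic; the hill-climb additionally keeps the *projection* of the learned
graph (ignoring the lag) acyclic, mirroring static Bayesian-network
semantics, with autoregressive self-links exempt.

A related convention: a node with lag-1 parents has no first-year
emission (the usual conditioning of AR likelihoods on the first
observation), and a missing value removes that node's emission factor for
that year — and its contribution to the M-step — rather than being
imputed. Exact marginalization over a missing continuous *parent* would
require joint Gaussian inference across the whole slice; dropping the
factor is the conservative choice and matters little in practice because
the tables this targets are complete.

## The three competing structures

The pipeline compares three hypotheses about what drives the system,
encoded as network families:

* **ARHMM** — one shared binary hidden chain with an intra-slice edge to
  every observed node; every observed node keeps a lag-1 self-link and has
  no other parents. Dynamics are "own past plus regime".
* **ARDBN** — two hidden chains, one attached to the basin-scale climate
  index (`HV_AMO`) and one to the regional sea-surface-temperature (SST)
  series (`HV_SST`); every observed node keeps its self-link; every
  *response* variable additionally receives its single highest-confidence
  learned parent.
* **DDDBN** — the same two hidden chains; self-links retained only for
  climate and physiochemical drivers; each response variable receives its
  top-confidence learned parents up to three parents in total. Dynamics
  are "ecosystem interactions plus regime", with no autoregressive crutch
  for the biology.

Climate and physiochemical variables are inputs throughout: they are
modeled (so the network can filter and propagate through them) but never
scored.

When a learned dependency originates from the hidden-state column (see
below), the builders must decide which of the two chains carries it. The
package attaches it to `HV_SST`, except for an edge into the AMO node
itself, which goes to `HV_AMO`. This allocation is a package convention —
the alternative (splitting by the child's correlation with each chain) adds
a tuning step without changing any structural rule. Ties in confidence are
broken toward the lexicographically smaller parent name so builds are
reproducible. In the DDDBN, a response variable none of whose candidates
reaches the confidence threshold (0.5 by default) falls back to its single
best-scored parent, so every response stays predictable from something.

## Structure learning

Dependencies are learned by greedy hill-climbing over lag-1 parent sets,
scored by the node-wise Gaussian BIC

$$ \mathrm{score}(v) \;=\; \widehat{\ell}_v \;-\; \tfrac{k_v}{2}\,\log n, $$

where $\widehat{\ell}_v$ is the maximized log-likelihood of regressing
$x_t[v]$ on its parents' year-$(t-1)$ values and
$k_v = |\mathrm{parents}| + 2$ (intercept and variance included). The
score decomposes over nodes, so moves (single-edge addition, deletion,
reversal) re-score at most two families; the implementation caches
per-child add/delete score columns and a per-step transitive closure of
the projected graph, which keeps a 28-variable window search under a tenth
of a second. Parents are capped at three, matching the DDDBN's cap.

Search runs on sliding windows (default 10 years, stride 1) with random
restarts (default 10), and the **edge confidence** of a directed edge is
the fraction of window $\times$ restart runs whose local optimum contains
it — 230 runs on a 32-year series. The hidden state learned by the ARHMM
enters the search as a continuous column (its smoothed posterior
probability of the high state), so regime-driven co-movement can be
explained by the regime column instead of surfacing as spurious
series-to-series edges. Window length, stride and restart count are not
printed anywhere authoritative; the defaults were fixed once at these
desk-scale values and the confidence estimates are insensitive to the
stride at this series length.

One caveat the synthetic experiments make explicit: series that share a
hidden driver (the climate block) are genuinely dependent *marginally*,
so edges among them are not "spurious" even though the generating model
has none — conditional independence given an unobserved state is
invisible to any observable-only score. Recovery checks therefore compare
planted parents only against false parents of children whose complete
parent sets are observed (the biota and physiochemical series).

## Parameter estimation

Given a structure, parameters are estimated by EM over the hidden chains.
The E-step runs exact forward-backward over the joint state space of all
chains (at most $2^2 = 4$ states here), accumulating smoothed state
marginals, pairwise transition expectations, and responsibility-weighted
regression cross-products per node and configuration. The M-step solves
the weighted normal equations per configuration (1e-8 ridge on singular
systems), floors variances at $10^{-6}$ (standardized units squared),
normalizes transition rows from expected counts with a $10^{-3}$
pseudocount, and keeps a configuration's previous parameters when its
responsibility mass is numerically zero.

Initialization matters more than anything else in this model class.
Independent per-year random responsibilities collapse onto a regime-free
local optimum essentially always — averaged over years they contain no
temporal signal for the chain to latch onto. The package therefore starts
the first run from a 2-means clustering of each chain's observed children
(the standard initialization for Gaussian regime models) and the remaining
runs from random *sticky* state paths (stay probability 0.85, soft
assignment 0.7). With this scheme, on 500-year planted series the median
error of the recovered transition diagonal is ~0.02 and of regression
weights ~0.02; with i.i.d. random starts the fit reliably lands hundreds
of log-likelihood units below the generating model. Convergence is
declared at a relative log-likelihood change of $10^{-6}$ (default), and
the best of `n_inits` starts is returned with hidden states relabeled so
state 1 has the smaller first-child intercept.

## Predictive evaluation

Models are compared by one-step-ahead prediction under a non-parametric
bootstrap (250 iterations in the full protocol). Each iteration draws 32
year indices with replacement; the never-drawn years (on average a
fraction $(1 - 1/32)^{32} \approx 0.362$) form the test set. Because a
Markov chain needs contiguous time, "training on the resampled years" is
implemented as *weighted* EM: each year's emission terms are weighted by
its bootstrap multiplicity, out-of-bag years contribute no evidence (their
emissions are marginalized, exactly as missing data), and the chain runs
over the full series. This respects the resampling protocol without
fabricating a shuffled time axis.

Each out-of-bag year $t$ is then predicted from the *observed* evidence at
$t-1$: the hidden prior is the filtered posterior at $t-1$, propagated one
step through each chain's transition matrix, and each observed node
reports its mixture mean and total-variance mixture spread. Per-variable
SSE is summed over a bootstrap iteration's test years and averaged across
iterations (the pooled sum is also reported — the two differ only by the
factor 250); 95% bands are bootstrap mean $\pm 1.96$ sd. Structure is
learned once on the full table; only parameters are re-fit per iteration.
Re-learning structure inside every iteration is possible via the
`structure_fn` hook of `evaluate_model()` but is not the default, since
the comparison targets fixed structural hypotheses.

## Temperature press scenarios

A press of $\Delta$ °C adds $\Delta / s_v$ to each SST series $v$ on the
standardized scale, where $s_v$ is that series' original-unit standard
deviation — presses are physical quantities, converted per series (a
`scale = "standardized"` option bypasses the conversion). Training is
untouched; only the prediction pass changes. The press pass filters the
hidden chains on the perturbed SST evidence (the SST regime chain must be
allowed to respond) and shifts the prediction evidence: SST columns by the
fixed press, and every other column by the press-induced shift of its own
prediction in the previous year. This recursion is what makes indirect
responses possible at all — with lag-1 edges and strictly original
evidence, nothing two hops from SST could ever move, contradicting both
the reachability intuition and the reported behavior of such systems. In
a purely linear network the recursion yields exactly the sum over directed
SST-to-target paths of path-weight products (geometrically damped by the
one-year evidence delay), which is what the scenario tests verify, along
with dose-response monotonicity across the 1.0/1.5/3.0 °C presses and
exact doubling under a doubled press. AMO and dissolved oxygen are never
perturbed: the former because its relation to a warming trend is not
identified, the latter because the SST-to-oxygen dose is unknown — both
respond only through the network, if at all.

## The synthetic test bed

`synthetic_spec()` defines the generating systems used everywhere a ground
truth is needed. The default mirrors the shape of the Gulf of Mexico application: 32 years, 4
climate series (3 of them SST-like, switched by one persistent binary
regime with a 1.5-sd mean shift and stay probability 0.9), 6
physiochemical series (autoregressive), and 18 biota series, each with 1–3
planted lag-1 parents drawn from drivers and earlier biota (never biota
into climate), weights of magnitude 0.4–0.8 with random signs, and
Gaussian noise of sd 0.5. These values were chosen once as representative
of standardized ecological indicator series — regime shifts visible but
not trivial, dependencies strong enough to matter at $n = 32$ — and are
not revisited by any test. Recovery experiments use longer series (300–500
years) because consistency, not small-sample luck, is what they check.

What the generator does *not* emulate: observation gaps, non-Gaussian
tails, lag-2+ dependencies, seasonal structure, and regime switching in
the biology itself (only climate is switched). Passing tests therefore
demonstrate correctness of the machinery under the stated model class, not
that real monitoring data satisfy that class.

## Problem sizes and numerical choices

Test and acceptance runs use: toy chains of 3–8 years for enumeration
oracles (exact to 1e-8), 500-year series over 5 nodes for parameter
recovery, 300-year series over 13 nodes for structure recovery, and the
full 32 x 28 survey-scale table with 250 bootstrap iterations for the
three-model comparison — sizes chosen so the whole suite exercises every
claim at desk scale. Variance floors ($10^{-6}$), the transition
pseudocount ($10^{-3}$), the ridge ($10^{-8}$) and the greedy
tie-threshold ($10^{-9}$) are the only magic numbers in the numerics; each
exists to keep a well-defined quantity away from an exact boundary, not to
tune results.

## Known limitations

* Hidden chains are binary; more regimes would require generalizing the
  configuration indexing (the joint-state machinery already supports it in
  principle).
* The conditional-likelihood treatment of missing parent values discards
  a little information relative to full joint-Gaussian marginalization.
* Edge confidences conflate windows and restarts into one denominator;
  if the distinction matters, run `hill_climb()` per window directly.
* The press recursion propagates means only; press-induced variance
  inflation reaches the bands only through the bootstrap spread of the
  refits, not through the mixture variance.
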