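---
title: "Spike dynamics and attractor embedding on strongly connected digraphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike dynamics and attractor embedding on strongly connected digraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgdyn)
```

## The model

`scgdyn` studies a deliberately minimal model of a strongly connected
directed network (an *SCG*) of excitable-refractory units.  Each vertex is
a unit that, when stimulated, emits an instantaneous spike and then sits in
a refractory state for a fixed period $\delta > 0$ during which further
stimulation has no effect.  Each directed edge $(i, j)$ carries a positive
transmission lag $\ell_{ij}$: a spike at $i$ arrives at $j$ after
$\ell_{ij}$ time units and makes $j$ spike immediately — unless $j$ is
refractory, in which case the arrival is discarded.  Spikes are treated as
instantaneous because the lags (here drawn uniformly from $[50, 100]$) are
assumed large compared with the spike width.

This idealisation replaces a continuous excitable-refractory vertex
dynamic (Hodgkin–Huxley or FitzHugh–Nagumo type) with pure event
book-keeping: it is enough to track firing times, pending arrivals and
refractory windows.  Continuous membrane dynamics, inhibition, synaptic
failure and spike amplitudes are deliberately out of scope.

Once a single kick spike is injected at $t = 0$, a strongly connected
graph passes activity around its cycles indefinitely (or the activity dies
out when every return path is blocked by refractoriness).  The long-run
behaviour is typically quasi-periodic — a winding dynamic on a torus
$T^\mu$ — and the package's central measurement is an upper bound $m$ on
the attractor dimension $\mu$, read off the inter-spike intervals observed
at one vertex.

## Event-driven simulation and its conventions

`run_free()` and `run_forced()` process a priority queue of pending
arrivals.  The model statement leaves boundary behaviour open, so the
package fixes these conventions:

* **Refractory boundary.** The refractory window after a spike at $t$ is
  half-open, $[t, t + \delta)$: an arrival at exactly $t + \delta$ fires.
  This makes $\delta$ an attainable minimum inter-spike interval and gives
  deterministic boundary behaviour; a directed cycle whose lag sum equals
  $\delta$ exactly sustains.
* **Simultaneity.** Arrivals at the same instant are processed in
  ascending vertex order.  Two simultaneous arrivals at one vertex cause a
  single spike — the second lands inside the refractory window just
  opened.
* **Start-up.** The kick is an ordinary arrival at $t = 0$; all histories
  and queues are empty before it.  Under periodic forcing the pulse train
  $0, p, 2p, \dots$ replaces the kick and obeys the same refractory rule.
* **Arithmetic.** Times are IEEE doubles and no rounding is applied; every
  spike time is exactly an upstream spike time plus an edge lag, which the
  test suite verifies by back-tracing.

A run ends when a spike cap is reached, a time horizon is passed, or the
queue empties (`died_out`) — the last is recorded as a status, not an
error, because the size survey needs to count such runs.

```{r two-loop}
g <- scg_graph(2, rbind(c(1, 2), c(2, 1)))
h <- run_free(g, lags = c(50, 60), delta = 20, max_spikes = 9)
as.data.frame(h)
```

The two-vertex loop fires with period `110` — the cycle's lag sum — at
both vertices, the simplest instance of the cycle arithmetic that drives
everything else.

## Estimating the embedding dimension

For a sustained run, `interspike_intervals()` extracts the interval
sequence $q$ at one vertex after discarding a burn-in fraction (default
20% of that vertex's spikes) so that the analysed stretch sits near the
attractor.  `embedding_dimension()` then applies singular spectrum
analysis with embedding delay one interval:

1. `trajectory_matrix()` stacks the $N = |q| - k + 1$ sliding windows
   $(q_i, \dots, q_{i+k-1})$ as rows (default $k = 80$);
2. `isi_spectrum()` takes the eigenvalues
   $\lambda_1 \ge \dots \ge \lambda_k \ge 0$ of the *uncentered* second-
   moment matrix $X^\top X / N$;
3. `detect_break()` finds the spectral break: eigenvalues are clamped at
   a floor of $10^{-14}\lambda_1$, and $m$ is the last position whose
   log-gap $\ln\lambda_m - \ln\lambda_{m+1}$ exceeds $\theta = 2$.

Three of these choices deserve justification.

**Uncentered windows.** With the mean retained, a perfectly periodic
(constant-interval) system has a rank-one spectrum and reports $m = 1$,
consistent with reading $m$ as the dimension of a Euclidean space
containing the attractor ($T^\mu$ embeds in $\mathbb{R}^{\mu+1}$; a fixed
point needs one coordinate).  Centering would report $m = 0$ there.

**The floor.** A symmetric eigendecomposition in double precision
resolves eigenvalues down to roughly $k \cdot \varepsilon \approx
2\times10^{-14}$ relative to $\lambda_1$; below that, values are round-off
and their logs are noise.  The floor sits just above this limit.  A higher
floor (say $10^{-12}\lambda_1$) silently truncates genuinely resolved weak
components: because $\lambda_1$ carries the squared mean interval, which
exceeds the fluctuation variance by several orders of magnitude, the
informative part of the spectrum lives many decades below $\lambda_1$.

**Last large gap, not largest gap.** For exactly the same reason, the gap
between $\lambda_1$ (mean) and $\lambda_2$ (strongest fluctuation) is
always large — typically 8–10 natural-log units in survey runs.  Taking
the globally largest gap would therefore report $m = 1$ for almost any
signal with small fluctuations about a large mean, masking clear
multi-component structure.  The quantity of scientific interest is the
*signal-to-noise separation*: the final drop onto the noise floor, below
which nothing further stands out.  `detect_break()` therefore returns the
last gap exceeding $\theta$.  When no gap exceeds $\theta$ the spectrum is
a gradual decay or plateau — the signature of broadband noise — and the
estimate is flagged `significant = FALSE` (the reported position is then
the largest gap, ties toward the smallest index).  The threshold
$\theta = 2$ (about a factor 7.4 between consecutive eigenvalues) is an
artifact parameter; quasi-periodic runs produce terminal gaps of 10–25
log-units, so the estimate is insensitive to $\theta$ over a wide range.

The calibration the suite enforces: $r$ incommensurate sinusoids around a
positive offset occupy exactly $2r + 1$ empirical orthogonal directions,
and `embedding_dimension()` returns $m = 2r+1$ for $r \le 3$ at
$N = 2000$, $k = 80$, matching an independent SVD oracle.

```{r ssa}
q <- 10 + sin(2 * pi * 0.618034 * (1:2000)) +
          sin(2 * pi * 0.414214 * (1:2000))
embedding_dimension(q, k = 80)
```

## Sampling strongly connected regular digraphs

Uniformly sampling large strongly connected digraphs with prescribed mean
degree is non-trivial — dense-enough random digraphs are rarely strongly
connected at $z = 3$.  `generate_scg()` runs a Markov chain instead:

* **Seed.** `seed_graph()` superposes $z$ edge-disjoint random
  Hamiltonian directed cycles, giving every vertex in- and out-degree
  exactly $z$ and guaranteeing strong connectivity.  The construction is
  deliberately contrived (long cycles, large diameter).
* **Moves.** Degree-preserving double edge swaps: replace $(a,b), (c,d)$
  by $(a,d), (c,b)$.  A proposal is rejected when endpoints coincide,
  when a proposed edge already exists, or when the swapped graph is no
  longer strongly connected — so every graph along the chain is
  irreducible with the same degree sequence, and the chain drifts from
  the contrived seed towards homogeneous graphs, typically shrinking the
  diameter.
* **Budget.** The default is $100 \cdot n z$ attempts, about 100 per
  edge — the usual mixing budget in degree-preserving edge-swap
  randomisation.  Attempts, not acceptances, are counted: rejection is
  part of the chain.

One divergence from the loosest reading of the target ensemble: the
sampled graphs are *exactly* $z$-regular rather than having expected
degree $z$.  This keeps the local structure identical across sizes, which
is the point of the size survey.

Vertices are numbered from 1, as throughout R.

## Entrainment under periodic forcing

`run_forced()` stimulates one vertex every $p$ time units.
`classify_entrainment()` asks whether the settled response is periodic
with period $K p$ for some integer $K$: in the tail of the run (last 25%
of the probe vertex's spikes), every spike at time $t$ must be matched by
a spike within `tol` (default 1 time unit) of $t + K p$, whenever
$t + Kp$ lies inside the observed range.  $K$ is searched in ascending
order up to `k_max = 8`, so the reported ratio is minimal, and the test
is by construction monotone in `tol`.

This *period-mapping* test is the direct operationalisation of "the
response has period $Kp$".  A seemingly natural alternative — clustering
tail phases modulo $Kp$ — misclassifies patterns whose phases happen to
coincide modulo $p$: the train $0, 30, 200, 230, \dots$ under $p = 100$
has phases $\{0, 30\}$ modulo 100 yet has true period $200$, which the
period-mapping test identifies as 2:1.

On high-dimensional instances, entrainment is sparse: scans find robust
1:1 and 2:1 locking when $p \lesssim \delta$ (the forcing then dominates
the refractory clock of the stimulated vertex) and scattered higher-order
locking windows at larger $p$, separated by wide non-entrained gaps.  The
classifier does not distinguish chaotic from higher-order-locked gaps.

## The size survey

`run_survey()` samples the conditional distribution $P(m \mid n, X)$: for
each size $n$ and replicate it generates a graph, draws lags, runs the
free dynamic and estimates $m$ at the kick vertex.  The fixed conditions
$X$ are $\delta = 30$, $z = 3$, lags uniform on $[50, 100]$, $k = 80$,
burn-in 0.2 — and the observation length, which the package fixes at
2000 post-burn-in intervals at the probe vertex for *every* $n$
($25 \cdot k$).  A shorter budget under-resolves the weak spectral
components of larger networks and biases $m$ downward at large $n$; a
budget growing with $n$ would confound size with observation length.
Each run's spike cap is sized as
$1.25 \, n \, (2000 + 1) / 0.8$ — vertices fire at equal long-run rates,
so this leaves the probe vertex its interval budget with margin.  Runs
whose probe vertex keeps fewer than $5(k+1)$ intervals (including
died-out dynamics) are recorded with `survived = FALSE` and excluded from
summaries, conditioning $P(m \mid n, X)$ on sustained activity; they are
rare under these conditions.

Child seeds are derived deterministically from (master seed, $n$,
replicate), so any subset of the survey reproduces independently.
`summarize_survey()` reduces the records to the five-number summary
(median, quartiles with linear interpolation, range) per size — the
quantities a box-and-whisker display shows.

At the survey's default conditions with 20 replicates per size on
$n \in \{25, 50, 100, 200\}$, the median $m$ grows with $n$ but far
slower than linearly (an 8-fold size increase yields roughly a 2–3-fold
median increase).  Medians of 20 replicates remain noisy — the spread of
$P(m \mid n, X)$ is wide, with an interquartile range comparable to the
median — so individual size-to-size comparisons can occasionally tie or
invert under reseeding even though the trend is robust.

## What the synthetic conditions do and do not show

All inputs are generated in-package: seeded random regular SCGs, uniform
i.i.d. lags, and synthetic quasi-periodic interval series for calibrating
the embedding step.  Passing tests therefore demonstrate internal
consistency of the model, the exactness of the event arithmetic, the
correctness of the SSA calibration, and the scaling behaviour *under this
model* — instantaneous spikes, a hard refractory wall, excitation-only
coupling, and lag distributions with no spatial or degree correlations.
They say nothing about biological spike trains, where noise, inhibition,
adaptation and correlated delays all violate the model's assumptions; the
embedding estimator in particular inherits SSA's sensitivity to
observational noise, which deterministic simulations do not exercise.

Numbers printed for a single instance (an embedding dimension, a mean
inter-spike interval, a graph diameter) depend on the realised graph and
lag draw; only distributional statements across seeds are stable.

## Problem sizes used by the checks

The test suite runs the simulator-versus-grid-oracle comparison on 100
seeded graphs with $n \le 8$ and quarter-integer lags (exact in binary, so
event times and tick arithmetic agree exactly); the rate-equality check on
20 sustained $n = 20$ runs of 20 000 spikes; and the survey at 20
replicates per size.  `scripts/acceptance.R` re-runs the reference
instance, the survey and a forcing scan from scratch at a caller-supplied
seed and writes the resulting quantities as JSON.
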