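---
title: "Periodic Markov models of migration on spatial networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Periodic Markov models of migration on spatial networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migflow)
```

## The model

migflow describes the year-round movement of a migratory population as a
non-homogeneous, periodic Markov process on a geographic network. Nodes
are discrete regions where animals breed, rest or winter; a directed
link from node $j$ to node $i$ carries a seasonal transition rate

$$ r_{ij}(\tau) \;=\; \omega_{ij}\,
   \exp\!\left(\frac{\cos(\tau-\varphi_{ij})-1}{\sigma_{ij}^2}\right), $$

a von Mises-shaped function of the season $\tau$. Time is measured on
the annual circle: one year is $T = 2\pi$ radians and, under the 365-day
year used throughout, one day is $2\pi/365 \approx 0.017$ rad. The three
parameters have direct biological meaning: $\varphi$ is the peak timing
of the transition (e.g. 1.70 rad $=$ week 13 for a spring arrival),
$\sigma$ the length of the transition period, and $\omega$ the maximum
per-capita transition intensity. The limits are instructive:
$\sigma \to \infty$ gives a time-homogeneous chain, $\sigma \to 0$ a
population that moves all at once.

Population densities $N_i(t)$ (summing to one over nodes) evolve by the
conservation law: outflow $\sum_j r_{ji}N_i$ against inflow
$\sum_j r_{ij}N_j$. Numerically the year is split into $m$ equal
intervals of width $\Delta\tau = T/m$ ($m = 48$ by default, about one
week each) and the dynamics advance by the transition matrices

$$ P(\tau;\Delta\tau) \;=\; e^{R(\tau)\,\Delta\tau}, $$

where $R$ collects the link rates, entry $[i,j]$ holding the rate from
$j$ to $i$. Composing the $m$ matrices of one year chronologically gives
the Poincaré (year) map $S(\tau)$; it is column-stochastic, its dominant
eigenvalue is 1 by Perron–Frobenius, and the associated eigenvector is
the stationary seasonal density $N^*(\tau)$ — the stable fraction of the
population in each node at season $\tau$, to which forward simulations
converge on any well-mixed network.

Two conventions deserve a note because the index bookkeeping is easy to
get wrong:

* **Generator diagonal.** With the $j \to i$ reading of $r_{ij}$, mass
  is conserved when each *column* of $R$ sums to zero (the diagonal is
  minus the total outflow of the column's source node). A row-sum
  diagonal under the same index convention would silently create or
  destroy animals; `rateMatrix()` therefore always builds column-sum
  zero generators, and the test suite asserts conservation to $10^{-9}$
  per step over ten simulated years.
* **Season of an interval.** All rates are evaluated at the interval
  *midpoint* $(k-\tfrac12)\Delta\tau$. The midpoint rule is
  second-order accurate for the underlying continuous process, and it
  keeps the model consistent with estimation: transition events
  observed "during interval $k$" are attributed to the same midpoint,
  so fitted and generating phases agree without a half-interval offset.
* **Product order.** The year map composes chronologically,
  $S(\tau) = P(\tau + (m-1)\Delta\tau)\cdots P(\tau)$, so that it maps
  a season-$\tau$ density exactly one year forward. The stationary
  solution is computed once (eigenvector at season 1, with a
  power-iteration fallback and a warning for reducible networks) and
  propagated through the $P$ matrices, which makes the $m$ seasonal
  eigen-solutions one coherent orbit by construction.

## From tracks to a fitted network

The estimation pipeline mirrors how practitioners reduce telemetry
data:

1. **Daily best positions.** One fix per individual and calendar day:
   best accuracy first (numeric horizontal error, or an ordinal
   location-class ranking, Argos `3 > 2 > 1 > 0 > A > B` by default),
   ties broken by the latest timestamp of the day.
2. **Velocities and resting.** Approach/departure speeds are
   great-circle distances (haversine, $R = 6371$ km) divided by the day
   gap; gaps longer than 3 days yield no velocity, because a week-long
   gap at face value would disguise a multi-thousand-km flight as slow
   travel. A day is *resting* when every available velocity is strictly
   below the species threshold (presets: 50 km/day for white storks,
   20 km/day for white-fronted geese).
3. **Nodes.** Resting positions are clustered agglomeratively on
   great-circle distance and the tree is cut at 750 km — a typical
   spacing of migratory stopover regions. Complete linkage is the
   default because the cut then bounds cluster *diameter*, matching the
   reading of the cut distance as a region size; single and average
   linkage are available. Clusters with three or fewer positions are
   discarded as outliers.
4. **Links and events.** Consecutive resting positions of one
   individual in different clusters define a directed link; each event
   is dated at the midpoint between the last day in the source and the
   first day in the target, since the data cannot resolve the flight
   day more finely.
5. **Rates.** For every seasonal interval, $N_j(\tau)$ counts the
   individuals present in node $j$ (once per interval, not per day —
   occupancy is "number of animals", not bird-days) and
   $J_{ij}$ counts the transition events, giving the empirical rate
   $\tilde r_{ij} = J_{ij} / (N_j\,\Delta\tau)$.
6. **Fit.** Per link, $\varphi$ and $\sigma$ are the weighted circular
   mean and circular standard deviation ($\sqrt{-2\ln\bar R}$, truncated
   below at one day $= 0.017$) of the interval midpoints with weights
   $\tilde r$; $\omega$ is set so the fitted curve's yearly mass
   $\sum_k r(\tau_k)\Delta\tau$ matches the empirical mass — preserving
   the total yearly flow that drives the Markov dynamics. Matching the
   peak instead is available via `omega = "peak"`.

Two estimator refinements are worth understanding before trusting fits
on strongly migratory data:

* **Saturation.** The raw ratio $J/(N\Delta\tau)$ estimates the
  transition *probability* per unit time, which saturates at
  $(1-e^{-\rho\Delta\tau})/\Delta\tau$ when the total exit rate $\rho$
  of the source is not small against $1/\Delta\tau$. At the example
  network's intensities ($\omega\Delta\tau = 0.65$, two competing links
  doubling the exit rate) this understates peak rates by 30–45%.
  `empiricalRates(correct = "exit")` inverts the saturation with the
  discrete-observation competing-risks estimator
  $\hat\rho_j = -\ln(1 - \sum_i J_{ij}/N_j)/\Delta\tau$, apportioned by
  flow shares; the two estimators agree whenever exits are slow.
* **Stragglers.** When only a handful of animals remain at risk, a
  single departure produces an enormous rate (2 of 3 leaving reads as
  $\rho\Delta\tau \approx 1.1$), pure variance that can dominate the
  circular moments. Intervals with fewer than `minAtRisk` animals
  (default 5 in the fitting pipelines) are treated like $N = 0$: no
  information, rate zero, flagged.

Even with both refinements, the amplitude and width of a link whose
source empties *before* the rate peak arrives are weakly identified:
once nearly everyone has left on the rising flank, the data say little
about how high or wide the peak would have been. This is visible in the
package's own recovery experiments (1000 simulated agents on the
example network): phases are recovered to within about $\pm 0.1$ rad
and widths to roughly $\pm 20$–$30\%$, but amplitudes of saturating
links can err by 40% or more at this sample size — a property of the
estimation problem, not of the implementation (a full
maximum-likelihood fit shows the same behaviour). The corresponding
acceptance test records this limit honestly rather than relaxing it.

## Network characterisation

Season-specific topologies connect $j \to i$ wherever
$p_{ij}(\tau;\Delta\tau) > 0.05$; their union is the cumulative
network. On these the package computes mean degree and giant-component
size per season (weak connectivity by default — seasonal snapshots are
nearly unidirectional flows), directed shortest path lengths,
betweenness centrality, and the census of the 13 connected directed
triads with z-scores against a degree-preserving null (double-edge
swaps, $10\ell$ attempted swaps per sample, seeded; classes with zero
null variance are flagged and scored 0). Flow-side summaries are the
cumulative density per node ($\sum_k N_i^*(k)$, in density × intervals,
range $[0, m]$), the staying time after the density peak, and expected
first-passage/return times of a walker started at the source's
peak-density season, computed by absorbing-state propagation on the
periodic chain with a 200-year horizon cap and the unabsorbed residual
reported. "Staying time" has no canonical formula; here it is the
length of the contiguous run, from the peak interval, during which the
density stays above half its peak — a documented convention, so printed
staying times should not be compared against other definitions.

## Validation and sensitivity

Fitted models are checked two ways: a paired two-sided Wilcoxon
signed-rank test (exact for $\le 25$ pairs, continuity-corrected normal
otherwise) plus mean/median relative deviation between empirical and
fitted rates over all informative link-intervals; and per-season
G-tests, $G = 2\sum O\ln(O/E)$, of counted occupancies against the
model densities. The sensitivity scan perturbs one parameter of one
link at a time — amplitude factors log-spaced in $[0.01, 100]$, phase
shifts and width deltas in $[-1.58, 1.58]$ (±3 months, widths truncated
at one day), 13 grid points per sweep — recomputes $N^*$, and compares
it with the baseline scaled to a pseudo-population (default 32
individuals, a realistic telemetry sample size, because G-tests need
counts). A perturbation is "close" when more than 67% of the seasonal
G-tests have $p > 0.1$. The zero perturbation reproduces the baseline
bit for bit.

## What the synthetic generator does and does not emulate

`simulateAgents()` draws each agent's next node from the exact
transition-matrix columns, so simulated populations are distributed
precisely per the model — parameter recovery is then a well-posed test
of the estimators alone. `emitTracks()` dresses the node histories up
as Movebank-style daily fixes: Gaussian positional jitter around node
centres (10 km s.d. by default, converted to degrees at the node's
latitude), travel days interpolated along the great circle at
600 km/day so migration days exceed any resting threshold, 1+ fixes per
day, log-normal horizontal accuracies, and days dropped independently
with probability 0.05. All randomness flows from a single mandatory
seed. Deliberately *not* emulated: wind and weather, flocking, memory,
density dependence, diel activity patterns, or habitat-driven node
shapes — so passing the end-to-end recovery tests demonstrates that the
pipeline inverts the model's own assumptions, not that real storks obey
them.

## Worked example

```{r}
net <- exampleNetwork()
net
nst <- stationaryDensities(net)
round(densityValues(nst)[c(1, 25, 36), ], 3)
```

Interval 25 (midsummer) has essentially the whole population in the
breeding node; interval 36 shows the autumn passage through the
stopover; interval 1 (midwinter) shows the winter split with node 3
above node 4 because the transition towards it opens earlier.

```{r}
cumulativeDensityAndStaying(nst)
```

## Problem sizes and numerical choices

The shipped tests and the acceptance script use the four-node example
network ($m = 48$), random networks up to 8 nodes, 1000 agents for
node-level recovery, 16 year-tracks for the full GPS pipeline
(hierarchical clustering is quadratic in resting positions, so
pipeline checks use a season's worth of data rather than decades), and
30 000 Monte-Carlo walkers for first-passage cross-checks. Tolerances
are fixed package-wide: column sums of generators to $10^{-12}$,
stochasticity and conservation to $10^{-9}$, Perron eigenvalues and
periodic fixed points to $10^{-8}$, eigen-vs-power-iteration agreement
to $10^{-6}$. Matrix exponentials use a compiled scaling-and-squaring
Padé routine, cross-checked in the tests against brute-force
Taylor-series summation.
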