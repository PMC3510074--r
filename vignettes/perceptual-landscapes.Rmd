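---
title: "Perceptual landscapes and the average-animal null model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perceptual landscapes and the average-animal null model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(plandscape)
library(dplyr)
```

# The problem

Tracking systems that detect animals only at discrete sites — RFID readers
on nest-box entrances, PIT-tag antennas at feeders, camera traps — produce
*stay events*: intervals during which one animal is known to be inside one
site, and nothing in between. Two questions follow naturally:

1. **Space use.** What does the habitat look like *to the animals*? Between
   two detections an animal was somewhere, and how long it took to reappear
   says something about how freely it moved; how long it stays at a site
   says how attractive that site is.
2. **Sociality.** Animals that are in the same box at the same time meet.
   How much of the observed "social structure" (who meets whom, how often,
   for how long) needs behavioural explanation at all, and how much is what
   identical, memoryless walkers on the same sites would produce anyway?

`plandscape` answers both: it builds a *perceptual landscape* — a potential
surface over the habitat whose valleys are well-used space — from stays and
transits, and it implements the corresponding *average-animal* stochastic
null model with the statistical machinery to compare it against data.

# The movement model

## Bridges between sites

A transit from site $i$ to site $j$ of straight-line length $L$ and
duration $T$ is modelled as planar motion with a constant drift
$v_\mathrm{drift} = L/T$ plus isotropic diffusion with coefficient $D$
(a Brownian bridge with drift). The model has one free speed scale: the
*effective speed* $\bar v$, the assumed along-path speed of a moving
animal. At arrival the mean square displacement of the drift–diffusion
motion, $v_\mathrm{drift}^2T^2 + 4DT$, is equated with $(\bar v T)^2$,
giving the per-bridge diffusion coefficient

$$D = \frac{\bar v^2 - (L/T)^2}{4}\,T .$$

$\bar v$ is calibrated from the data: the bridge with the largest
$L/T$ (the "straightest" bridge) is assumed to have been crossed in a
straight line, so $\bar v = \max_{ij} L_{ij}/T_{ij}$ and every bridge
receives $D \ge 0$, with equality exactly on the straightest one.
Because transit-time distributions are heavily right-skewed (rare
day-long excursions), each site pair is summarised by the *median* of its
pooled transit durations — `distribution_summary()` reports the
mean/median tail ratio that motivates this choice — and pairs crossed
fewer than `min_crossings` times (default 50; 10 for individual animals)
are discarded as under-sampled.

Sites are not points, so each bridge endpoint carries a positional
variance; the default standard deviation is half the site radius. The
per-axis variance along a bridge is

$$\sigma^2(t) = 2Dt\Big(1-\frac{t}{T}\Big)
  + \Big(1-\frac{t}{T}\Big)^2\sigma_s^2 + \Big(\frac{t}{T}\Big)^2\sigma_e^2,$$

equal to the endpoint variances at $t = 0, T$ and peaking at $T/2$ for
symmetric endpoints. The position density at time $t$ is an isotropic
Gaussian with that variance, centred on the drift position; integrating
it over the transit, $\rho(x,y) = \frac1T\int_0^T p(x,y,t)\,dt$, gives
the bridge's static footprint. Summing footprints over all bridges,
weighted by crossing counts, yields the stationary occupancy density $P$,
and the *dynamic landscape* is its canonical potential (in $k_BT = 1$
units):

$$u_d = -\ln (P/P_{\max}).$$

## Wells at sites

Residence is modelled as pure diffusion inside a circular potential well
of radius $a$ (the site radius). The radial coordinate collects both
planar axes, $D_r = 2\bar D$, where $\bar D$ is the crossing-weighted
mean of the bridge diffusion coefficients. For a well of depth
$\Delta u$ the Kramers/Klein mean first-passage time out of the well is
$\tau \approx \frac{2\pi\gamma}{\omega_0\omega_b}
e^{\Delta u/(\gamma D_r)}$, which the package inverts at each site's
*mean* stay duration (a mean first-passage time is a mean, so the median
is deliberately not used here):

$$\Delta u = \gamma D_r
  \ln\!\Big(\frac{\omega_0\omega_b\,\tau}{2\pi\gamma}\Big),
  \qquad \text{clipped below at } 0 .$$

$\gamma$ (friction) and $\omega_0, \omega_b$ (bottom and rim curvature
frequencies) default to 1 and act purely as height scalings; they are
exposed because plotting wells against a strong dynamic relief can
require rescaling the nesting component.

The full perceptual landscape is the cell-wise sum $u = u_d + u_w$ of the
dynamic and nesting components. It is defined up to an additive constant:
only height differences are meaningful, and all package tests compare
differences.

## The well profile and its escape-law convention

The radial profile is quadratic at both stationary points ($u(0) =
-\Delta u$, $u(a) = 0$, zero slope at both), joined by a monotone cubic
Hermite segment; given the radius, the construction is governed by the
depth alone under default curvatures. One convention had to be fixed:
with a reflecting centre and an absorbing rim, *both* saddle-point
integrals of the exact mean-first-passage-time formula are half-Gaussians,
which multiplies the classical mid-barrier prefactor by 4. The package
therefore sets the cap curvatures to $u''(0) = \gamma\omega_0^2/4$ and
$|u''(a)| = \gamma\omega_b^2/4$, which makes the constructed well satisfy
the $2\pi\gamma/(\omega_0\omega_b)$ escape law it inverts. This is a
convention, not a fit: it was chosen once against the exact
double-integral oracle (`well_escape_time_quad()`), which agrees with the
inverted law to within ~2% for $\Delta u/(\gamma D_r)$ between 3 and 6
and ~4% at 2, and the Euler–Maruyama simulator (`simulate_escape()`,
compiled code) confirms it stochastically. Outside that band the
Arrhenius form degrades as saddle-point approximations do — shallow wells
($\Delta u \lesssim \gamma D_r$) escape faster than the law suggests, and
`well_depth()` clips them at zero depth.

# The average-animal null model

The social null hypothesis is that every animal is the same memoryless
walker on the state space {in box $i$} $\cup$ {in transit $i \to j$},
with rates pooled over the whole population:

* `estimate_rates()` fits the competing-risks rates
  $r_{ij} = (\text{departures } i\to j) / (\text{total stay time in } i)$
  — so the total leave rate of a box is the inverse of its mean stay
  duration, destinations carry their empirical frequencies, and rates
  estimated from the model's own output converge back to the model — and
  transit-completion rates as inverse mean transit durations. A
  `paper_normalise` flag rescales each matrix to unit sum, a pure change
  of time unit kept off by default so simulated durations stay in
  seconds.
* `simulate_colony()` runs $N$ such agents with the exact Gillespie
  algorithm: exponential waiting time at the summed rate, one uniform
  draw mapped onto the cumulative per-agent rates to pick who moves
  (ties, which have probability zero, would resolve by agent index), and
  destination choice proportional to departure rates — equivalent to the
  race of competing exponential clocks, an equivalence the test suite
  checks. Agents start from the stationary distribution of the model's
  Markov chain.
* The emitted stays and encounters use exactly the observed-data schema,
  so metrics, landscapes and rate estimation run unchanged on simulated
  output.

The analytic companion (`build_generator()`, `stationary_distribution()`,
`relax_from_point()`) exposes the same model as a continuous-time Markov
chain over the $n + n^2$ states (dense linear algebra: even a 40-box
system has only 1640 states), including exit-and-return self-loop
transits. Agents in transit are "outside"; there is no separate loafing
state, so the state space is exactly boxes plus ordered transit pairs.

# Comparison machinery

`compute_metrics()` reduces stays and encounters to the behavioural
metric suite: per individual-day counts of stays, distinct boxes,
encounters and distinct partners; pooled stay and encounter durations;
mean individuals detected per day; and the global encounter rate,
(encounters/stays) divided by the mean stay duration. Days are
calendar windows (midnight-anchored by default, configurable origin and
length), and an individual contributes a day when it has at least one
stay starting in it.

`bootstrap_mean_test()` asks whether a simulated metric mean is
compatible with the observed distribution: the observed mean is
bootstrapped and the simulated mean compared with the central 95%
percentile interval, with a two-sided bootstrap probability. One
statistical subtlety is handled explicitly: a simulated mean computed
from a finite run carries sampling noise too. Under the null that it is
the mean of an independent sample of size $n_\mathrm{syn}$ from the same
distribution, the difference of means has variance
$\sigma^2(1/n + 1/n_\mathrm{syn})$, so the bootstrap distribution is
widened by $\sqrt{1 + n/n_\mathrm{syn}}$ before comparing. With the
default $n_\mathrm{syn} = n$ the test rejects a true null at the nominal
5%; with $n_\mathrm{syn} = \infty$ it reduces to the plain percentile
interval, appropriate when the simulation is so long that its mean is
effectively exact. `compare_metrics()` applies this per metric and
reports a tidy table (plus a Shapiro–Wilk normality diagnostic of the
simulated distribution, which gates nothing). No multiplicity correction
is applied across the suite, by design: each metric is reported on its
own.

# The synthetic-colony generator

Real deployments cannot ship inside a package, so `generate_colony()`
builds colonies with *known truth* that reproduce the structural features
the methods care about:

* sites in spatial clusters (territory segments) with cluster-biased
  destination preferences;
* per-box mean residence times on a shuffled geometric ladder spanning a
  configurable max/min ratio (default 20, mimicking the order-of-magnitude
  heterogeneity of real nest-box usage);
* *lognormal* transit durations (default log-SD 1.2) — deliberately
  heavier-tailed than the exponential transits the null model assumes, so
  the generator-vs-model mismatch mirrors the real-data situation and the
  median-based bridge summaries earn their keep;
* optionally, soft territoriality: each animal's destination weights
  outside its home cluster are damped by `1 - territory_strength`. Pooled
  rates then remain connected, but individual ranges are confined — the
  regime in which the homogeneous null model visibly overestimates the
  number of distinct boxes visited per day, its known blind spot.

The default "desk" scale (10 sites, 12 animals, 30 days) runs the whole
pipeline in seconds and is what the test suite and the acceptance script
use; a "barn" preset (40 sites, 76 animals, 2 years) mirrors a full
deployment. What passing the synthetic closure tests shows is that the
estimation-simulation-comparison loop is *self-consistent* under the
generator's assumptions (Markovian movement with heterogeneous
preferences and heavy-tailed transits); it cannot show that real animals
move this way — the territorial variant is precisely the demonstration
that they need not.

# Numerical choices

* **Rasters.** ESRI ASCII grids, cell-centre convention, south-to-north
  row storage in memory. Occupancy rasters store the *exact cell average*
  of the density (per-axis Gaussian interval masses), so probability mass
  is conserved even where a bridge endpoint (SD = half the site radius)
  is much narrower than a cell; a plain cell-centre sample would misplace
  a percent or more of the mass at the default 5 cm cells. Time
  integration uses 61-node Gauss–Legendre quadrature per bridge.
  `population_occupancy()` refuses rasters whose total mass deviates from
  1 by more than `mass_tol` (default $10^{-3}$) or that hold over 1% of
  the mass on the boundary ring.
* **Potential inversion.** Cells below $10^{-12} \times P_{\max}$ are
  capped at height $\ln 10^{12} \approx 27.6$; a finite raster needs a
  finite ceiling.
* **Point-wise occupancy.** `bridge_occupancy()` uses adaptive quadrature
  (absolute tolerance $10^{-8}\,\mathrm{m^{-2}}$) and errors if the
  tolerance is not reached.
* **Escape simulation.** Euler–Maruyama with reflection at 0 and
  absorption at $a$; the step (default 0.02 in the well's own time units)
  trades a small positive bias at the absorbing rim against runtime.
* **Well rasterisation.** Cells should satisfy `cellsize <= radius / 5`
  so the quadratic caps are resolved; the package warns otherwise.
* **Reproducibility.** Every stochastic entry point takes a seed;
  truth objects remember theirs, and trajectory generation derives a
  distinct stream from it so colony and trajectories can be varied
  independently.

# Worked example

```{r pipeline}
truth <- generate_colony(seed = 42)
stays <- generate_stays(truth)
encounters <- extract_encounters(stays)
transits <- stays_to_transits(stays)

pl <- build_landscape(stays, truth$layout, min_crossings = 50,
                      cellsize = 0.2)
glance(pl)
```

```{r landscape-plot, fig.height = 5}
autoplot(pl)
```

```{r nullmodel}
model <- estimate_rates(stays, transits)
sim <- simulate_colony(model, n_agents = truth$n_animals,
                       duration = truth$duration, seed = 43)
cmp <- compare_metrics(compute_metrics(stays, encounters),
                       compute_metrics(sim$stays, sim$encounters),
                       n_boot = 2000, seed = 44)
cmp[, c("metric", "obs_mean", "obs_sd", "syn_mean", "p_value", "inside")]
```

```{r cmp-plot, fig.height = 6}
autoplot(cmp)
```

# Known limitations

* The movement model is isotropic and per-bridge-homogeneous: one $D$
  per site pair (from the median transit), not one per crossing; no
  anisotropic diffusion, no barriers except as they emerge in the data.
* The null model deliberately ignores individual identity, sex, age,
  demography and social feedback — that is its point — and represents all
  out-of-box time as directed transits.
* Day-based metrics depend on the day-boundary convention; midnight
  anchoring is the default and configurable, but sub-daily rhythms are
  not modelled.
* The escape-law inversion is asymptotic: depths below about twice
  $\gamma D_r$ are noisy and are clipped at zero rather than trusted.
* Landscape heights are relative; comparing two landscapes means
  comparing shapes, not absolute values.
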