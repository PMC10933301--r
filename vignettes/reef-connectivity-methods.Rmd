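---
title: "Methods: larval dispersal, connectivity and consistent reef clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: larval dispersal, connectivity and consistent reef clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reefconn)
```

`reefconn` estimates *potential connectivity* between coral reefs — the
probability that a larva spawned at one reef settles at another, per
spawning event — by coupling Lagrangian particle tracking with a
mechanistic model of larval biology, and then analyses which reef clusters
persist across the stochastic variability of ocean currents. This vignette
is the package's own account of the model, its assumptions, the numerical
design, and what the synthetic test ocean does and does not demonstrate.

## 1. The larval dispersal model

### Advection

Coral larvae are treated as positively buoyant but otherwise passive
surface drifters: particle velocity equals the local surface current, with
no swimming, vertical migration, diffusion term or windage. Trajectories
are integrated with fixed-step 4th-order Runge–Kutta (default
`dt = 0.02` days in the full-science configuration; the demo pipeline uses
0.05 d), with bilinear interpolation of u/v in space and linear
interpolation in time. Velocities are in m s⁻¹ on a flat Cartesian grid in
metres by default; a degrees mode applies the standard 111 320 m/degree
metric with the cos(latitude) correction on the zonal axis. Particles are
released from every reef cell — at cell centres by default, or uniformly
jittered within the cell under a seed — and advected for up to
`T_max = 120` days, the standard pelagic-duration cap for broadcast-
spawning corals.

Boundary policy: a particle whose position falls in a land cell sticks
there with zero velocity (its biological state keeps evolving); a particle
leaving the open boundary is frozen at its last inside position, flagged,
and contributes no further reef occupancy. Sticking was chosen over
reflection because reflection manufactures spurious along-shore transport;
with zero-velocity land cells the interpolated field already decelerates
particles approaching the coast.

Cell occupancy uses half-open intervals `[edge_k, edge_{k+1})` on both
axes, so a particle exactly on an edge belongs to exactly one cell — the
convention every settling event depends on.

### Larval state

Each particle carries a cohort of larvae partitioned into a pre-competent
pool $L_1$ and a competent pool $L_2$ (proportions of the cohort, with
$L_1(0) = 1$):

$$\frac{dL_1}{dt} = -(\alpha + \mu_m(t))\,L_1, \qquad
  \frac{dL_2}{dt} = \alpha L_1 - (\beta + \mu_m(t) + \mu_s F_r(t))\,L_2,$$

with competency acquisition rate $\alpha$ (zero before the minimum
competency period $t_c$), competency loss rate $\beta$, mortality hazard
$\mu_m(t)$, settling rate $\mu_s$, and $F_r(t)$ the reef fraction of the
occupied cell. Mortality can be constant or Weibull,
$\mu_m(t) = \lambda\nu(\lambda t)^{\nu-1}$; shape $\nu < 1$ gives the
decreasing hazard typical of coral larval survival fits (the integrable
singularity at $t = 0$ is capped at $10^6$ d⁻¹, reported once).

A *settling event* is a maximal run of steps during which a competent-aged
particle ($t \ge t_c$) occupies one reef-bearing cell; a change of occupied
cell starts a new event, because each event needs a single destination
$F_r^j$. The larvae settling in event $j$ are

$$S_j = \frac{\rho A_i \mu_s F_r^j}{N}
        \int_{\tau_0^j}^{\tau_0^j+\Delta\tau^j} L_2(t)\,dt,$$

with fecundity $\rho$ (default 1 larva m⁻², so connectivity reads as a
proportion and $\rho$ cancels), source-cell area $A_i$, and $N$ particles
per cell. At most 60 events are kept per particle, earliest first.

### Parameters

| parameter | meaning | unit | default |
|---|---|---|---|
| $\alpha$ | competency acquisition rate | d⁻¹ | preset |
| $t_c$ | minimum competency period | d | preset |
| $\beta$ | competency loss rate | d⁻¹ | preset |
| $\mu_s$ | settling rate over full reef | d⁻¹ | preset |
| $\mu_m$ | mortality hazard (constant or Weibull) | d⁻¹ | preset |
| $\rho$ | fecundity | larvae m⁻² | 1 |
| `T_max` | pelagic duration cap | d | 120 |
| `max_events` | settling events per particle | – | 60 |

Two named presets are shipped, `"platygyra_daedalea"` (the usual stand-in
species when direct larval measurements are missing) and
`"acropora_valida"` (lower mortality, slower competency loss). Their values
are literature-informed approximations rather than direct transcriptions of
any single measured dataset, and nothing in the package's verification
depends on them: all quantitative tests run against closed forms or
synthetic fixtures with explicitly chosen rates.

## 2. Numerical design

The fate system is linear with time-varying coefficients. Within each
trajectory step, $F_r$ (left-endpoint value) and $\mu_m$ are frozen and the
**exact 2×2 propagator** is applied; the step integrals
$\int L_1\,dt, \int L_2\,dt$ come from the same closed form. Consequences:

- the only discretisation left is the piecewise-constant treatment of
  $F_r(t)$ and $\mu_m(t)$ along the trajectory;
- the larval mass balance (settled + dead + competency-lost + drifting =
  released) holds to round-off, and is asserted below $10^{-8}$ relative
  error in the tests;
- settling integrals are consistent with the propagator by construction,
  and match adaptive quadrature of the closed-form $L_2$ to $10^{-6}$
  relative error.

For the Weibull mode the per-step hazard is the *mean* hazard
$(H(t_1)-H(t_0))/(t_1-t_0)$ from the closed-form cumulative hazard
$H(t) = (\lambda t)^\nu$, which makes pure-death survival exact even across
coarse steps. Steps containing $t_c$ are split there, so competency
switches on at exactly $t_c$. The near-degenerate regime
$\gamma \to \alpha + \mu$ (where the textbook solution has a removable
singularity) is evaluated through series-stabilised helpers built on
`expm1`, verified at an offset of $10^{-9}$ d⁻¹.

RK4 on the solid-body rotation field — which bilinear interpolation
reproduces exactly, making the circular orbit an analytic oracle — shows
the expected 16× error reduction per halving of `dt` (asserted ≥ 8×), and
uniform-flow displacement is exact to round-off (0.1 m s⁻¹ over one day is
8 640 m).

## 3. Connectivity, season and the bootstrap ensemble

Summing $S_j$ over particles and dividing by larvae released
($\rho A_i$ per cell) gives $C[\text{source}, \text{destination}]$ per
spawning date — orientation is recorded in an `axis` attribute on every
matrix, because transposed connectivity matrices are the field's most
common bug. Cell-level matrices aggregate to reef groups by area-weighted
averaging of rows and summing of columns, which conserves row totals and
agrees exactly with accumulating at group level directly.

Spawning is daily within an October–March season (austral-summer coral
spawning); matrices outside the season are dropped, and an empty result is
an error pointing at the calendar. The stochastic ensemble follows the
mean-of-10 design: each of `n_rep = 1000` replicates (100 in the demo
configuration) is the arithmetic mean of `k = 10` spawning dates drawn
from the pool *with replacement* — the standard bootstrap; sampling
without replacement is available behind a flag. The replicate mean matches
the pool mean within Monte-Carlo error ($3\,\mathrm{sd}/\sqrt{n_{rep}}$
per entry) by construction, and this is asserted.

Two derived summaries:

- **Distance decay** — long-format table of directed group-to-group
  connectivity against centroid distance.
- **Generations to a common ancestor** — the connectivity matrix is read
  as a per-generation colonisation graph with an edge where
  $C \ge \varepsilon$, and $g(i,j) = \min_k \max(\text{steps}(k \to i),
  \text{steps}(k \to j))$ by BFS. The default
  $\varepsilon = 1/(\rho \sum A_i)$ ("at least one expected larva") is a
  package choice, stated as such. A group counts as its own 0-generation
  ancestor only when it self-recruits at $\ge \varepsilon$; otherwise its
  self-distance is its shortest directed return cycle. This refinement is
  needed for the definition to behave sensibly on chains (in
  $a \to b \to c$, the first common ancestor of $b$ and $c$ is $a$, two
  generations back — not $b$ itself).

## 4. Flow clustering and consistency

Each replicate matrix becomes a directed weighted graph (self-loops kept:
self-recruitment is within-module flow) and is partitioned by minimising
the **two-level map equation**

$$L(M) = q_\curvearrowright H(Q) + \sum_m p_m^\circlearrowright H(P_m),$$

the expected description length, in bits per step, of a random walk under
a two-level codebook. Visit rates come from power iteration (L1 tolerance
$10^{-12}$) on the row-normalised transition matrix mixed with **uniform
node teleportation** at rate 0.01; dangling nodes teleport with
probability 1. The codelength uses the flows of this full
teleportation-adjusted chain — the simplest published variant consistent
with a plain "1% teleportation" specification; recorded-link-teleportation
variants and hierarchical (multi-level) partitioning are out of scope.

The optimiser is greedy node-moving (candidates: neighbouring modules plus
a fresh singleton; ties to the lowest module id) alternated with pairwise
module merges, to a local minimum, best of 10 seeded restarts, never worse
than the one-module partition. At the graph sizes this package targets
(tens of reef groups) full codelength recomputation per candidate move is
cheap, so no incremental-update machinery or supernode aggregation is
used. Correctness is pinned by two independent oracles: a second,
independently written codelength evaluation (eigenvector stationary
distribution, explicit entropy loops) agreeing to $10^{-12}$ bits, and
exhaustive enumeration of all set partitions for every fixture graph with
≤ 8 nodes, which the optimiser matches exactly.

Module ids from independent runs are arbitrary, so before any cross-
replicate analysis each replicate's modules are renumbered 1..K in
decreasing total stationary flow (ties to the lowest original id). This
canonicalisation preserves co-assignment exactly and is the package's
answer to how categorical module ids can be made comparable across an
ensemble. The groups × replicates integer matrix then goes through a
centred (not scaled) PCA with groups as observations. PC1 separation
between groups is the consistency proxy: groups that always co-cluster sit
at the same PC1 score, and a persistent dispersal barrier appears as
disjoint PC1 score ranges. Encoding module *ids* as integers mirrors the
membership-vector-PCA design this package implements; a co-membership
matrix is a more conventional alternative and can be built from the same
membership matrix if a robustness check is wanted. When every replicate
agrees on a single module the membership matrix has zero variance; this is
flagged explicitly rather than letting NaNs propagate.

## 5. Gene-flow comparison

An observed site-by-site migration matrix (BayesAss-style: `m[i, j]` is
the fraction of population `i` derived from `j` per generation, rows
summing to 1, diagonal = self-recruitment) is compared pair-by-pair with
the modelled ensemble. No demographic conversion from potential
connectivity to per-generation migration is attempted — the comparison is
deliberately on the scale of orders of magnitude and feasible ranges: per
ordered pair the full ensemble, min–max, the 2.5/97.5% quantiles, the
log₁₀ ratio of observed to ensemble median, the centroid distance, and a
flag for observations exceeding the ensemble maximum. Both min–max and the
95% band are reported because which quantiles best define a "feasible
range" is itself a modelling choice.

The calibration of this machinery is checked in closed loop: when the
"observed" matrix is built *from* the ensemble (off-diagonals equal to the
ensemble-mean connectivity, diagonal as the residual to a row sum of 1),
at least 95% of pairs must fall inside the 95% band, and a planted 100×
inflation applied only to long-range pairs must be flagged only at long
range. The residual-diagonal construction keeps the off-diagonal entries
on the modelled scale; rescaling rows instead would defeat the purpose of
the range check.

## 6. The synthetic ocean, and what the tests do and do not show

No multidecadal hindcast is shipped or downloaded. The generators provide:

- **uniform** and **solid-body rotation** fields — pure oracles for the
  integrator;
- a **double gyre**: streamfunction-derived (hence divergence-free) two-
  cell flow on a 2L × L box, steady with an impermeable mid-domain
  separatrix at `perturbation = 0`, and with an oscillating (leaky)
  separatrix for `perturbation > 0`;
- clustered **reef grids** with F_r drawn from Beta(2, 2) — a stand-in
  distribution, chosen once, for unavailable satellite-derived reef
  fractions, truncated away from 0 so reef cells always have positive
  reef area;
- daily **spawning calendars** restricted to given months;
- planted-structure **gene-flow matrices** with configurable
  self-recruitment (default 0.8, inside the empirically typical 0.77–0.84
  band for reef corals) and within-block bias.

The demo pipeline (`default_config()`) places three reef groups on one
orbit in each gyre (10 cells per group, 3 jittered particles per cell, 12
spawning dates, 20–30-day drift, 100 bootstrap replicates) — sizes chosen
so the full pipeline runs in tens of seconds while every structural
property is still exercised. Groups share an orbit so within-gyre exchange
is robust; releases are jittered across the cell so trajectories sample a
band of streamlines rather than one closed curve. "Weak exchange" is
`perturbation = 0.15`, which makes inter-gyre transport appear at well
under 1% of within-gyre transport: a permeable barrier, not an open door.
At much stronger perturbation the inter-gyre flow grows to the point where
merging both gyres genuinely becomes the map-equation optimum — that is a
property of the map equation, not an optimiser failure (the optimiser
matches exhaustive enumeration there too), and it delimits what "weak"
must mean for a planted-recovery test to be meaningful.

What passing these tests shows: the integrator, the fate propagator, the
event accounting, the ensemble machinery, the partitioner and the
consistency analysis are each correct against independent oracles, and the
chain of them detects a planted barrier and grades its permeability. What
it does not show: anything about a real ocean. The synthetic fields have
none of the submesoscale variability, tides, coastal waveguides or
seasonality of a hindcast; reef fractions are a parametric stand-in; and
the larval presets are approximations. Conclusions about a real reef
system require real currents and real reef maps fed through the same
interfaces.

## 7. Reproducibility

Every stochastic component takes a seed; a single master seed is split
deterministically per consumer (`split_seed`), so one integer reproduces
the entire fixture suite. `run_pipeline()` writes all artifacts as plain
text (full-precision JSON for fields, grids and ensembles; CSV for
matrices) plus a manifest with the configuration, derived seeds and an md5
hash of every artifact; reruns with the same configuration are
byte-identical, and this is asserted in the tests. Persistence formats
round-trip exactly (17-significant-digit serialisation).

## 8. Known limitations

- No larval behaviour (vertical migration, orientation, swimming), no
  stochastic dispersion term, no Stokes drift: transport is purely the
  resolved surface current.
- No post-settlement mortality or density dependence; potential
  connectivity is therefore an upper bound on realised recruitment.
- Two-level partitioning only; no hierarchical module structure.
- The generations-to-ancestor summary treats the connectivity matrix as a
  stationary per-generation colonisation process, ignoring demography and
  temporal correlation.
- Land interacts with trajectories only as zero velocity; there is no
  coastline geometry below grid resolution.
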