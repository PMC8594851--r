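---
title: "The force vector model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The force vector model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`fvmsim` simulates opinion dynamics in a continuous, unbounded attribute
space. Each agent is a vector **A** from the origin; its components are the
continuous attributes that matter for the social question being modelled
(e.g. conservative--liberal on one axis, attitude toward some policy on
another). Two numbers complete an agent: an *active mass* m ("charisma"),
which scales the influence it exerts, and a *passive mass* M
("resistance" or stubbornness), which divides the influence it receives.

The force agent A exerts on agent B is

$$
\mathbf{F}_{A \to B} \;=\; g\, m_A \,
\frac{\mathbf{A}\cdot\mathbf{B}}{R^{p}} \, \frac{\mathbf{R}}{R},
\qquad \mathbf{R} = \mathbf{A}-\mathbf{B},
$$

with $R = \sqrt{\sum_k w_k (A_k - B_k)^2}$ the metric-weighted attribute
distance and $p$ the distance exponent (default 2, an inverse-square
law). The dot product sets the sign: agents whose vectors subtend less
than 90° attract (their attributes grow more similar), more than 90°
repel, exactly 90° exert nothing. Influence is gated by a confidence
bound, the *Attribute Influence Bound* (AIB): pairs separated by more
than the AIB in attribute space cannot interact at all. The force law is
deliberately asymmetric — it depends on the sender's active mass only —
unlike gravity.

Movement follows from integrating Newton's law over one time interval:
$\Delta\mathbf{B} = \mathbf{F}_{A \to B}\, (DT)^2 / M_B$. The model's
convention keeps no factor of ½; we implement the printed form exactly.
All displacements are computed from the pre-step state and applied
simultaneously.

Agents that end an iteration closer than the *Coalescence Radius* (CR)
merge into a permanent group located at the heaviest member, with summed
active and passive masses. Groups obey the same force law and can absorb
further agents; nothing ever splits a group.

### Adaptive time stepping

Each iteration first computes trial displacements at $DT = 1$; the
largest trial move is the *peak distance*. The realised step uses
$DT^2 = CR/\text{peak}$, so the fastest agent travels exactly CR and no
agent ever travels more. Weak forces therefore stretch the time step
(values of 100–170 are common late in large-AIB runs) instead of burning
iterations, and strong forces shrink it for smooth motion. The *elapsed
time* is the running sum of the $DT_i$. A useful corollary, which the
test suite asserts: trajectories are exactly independent of the force
scale $g$ — only elapsed time rescales, with $g\,ET^2$ constant.

### Termination

A run stops when (in the order checked): all pairs are separated by more
than the AIB; no agent would move (equilibrium, peak distance below
$10^{-12}$ model units — exact zero is fragile in floating point); a
`tickstop` iteration cap, an `agent_stop` population floor, or a
`dt_stop` bound on DT fires (each optional, 0 = off). The first
condition is checked before the step so a population born disconnected
stops with zero movement steps.

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `g` | 7e-5 | — | global force scale; trajectories are invariant to it under adaptive stepping |
| `distance_exponent` (p) | 2 | — | weight of short- vs long-range interaction; larger p localises influence |
| `aib` | 280 | model units | confidence bound; the central experimental dial |
| `coalescence_radius` (CR) | 0.2 | model units | merge distance and per-iteration displacement cap |
| `metric_weights` | 1, 1 | — | per-axis weights in the attribute distance |
| `force_mode` | NORMAL | — | sign post-processing (ablations: attract-only, zero-repulsive, ...) |
| `dimension` | 2 | — | attribute-space dimension; all formulas are componentwise |
| `visible_half_width` | 100 | model units | initialisation window; *not* a wall — agents that leave keep interacting ("ghosts") |

The visible window spans $[-100, 100]$ per axis; 280 is its diagonal, so
the default AIB lets any two visible agents communicate.

## Initial conditions: what the generator emulates

`standard_conditions(aib)` reproduces the baseline study conditions used
throughout: 100 agents, each coordinate drawn normal(0, 30) with draws
outside the window rejected and redrawn; masses normal(60, 15), rejected
above a cap or at zero or below; passive mass equal to active mass;
defaults for everything else. The samplers support uniform and
exponential families too, per-axis, and exact geometric arrangements
(square, triangle, ring) for symmetry work.

Choices the sources leave open, fixed here once:

* **Mass cap.** The baseline mass distribution needs a maximum; none is
  stated. We use 120 (mean + 4 SD), so truncation is symmetric around
  the mean together with the positivity cut and the realised mean stays
  60. The cap is exposed as `max_mass`.
* **Draw order.** Positions are drawn first (agent by agent, x then y,
  rejection per coordinate), then masses. This is implementation-defined
  but fixed, so a seed pins the whole population.
* **Exponential spatial family.** Parameterised one-sided from the lower
  window edge unless an offset is given; not used by the baseline.
* **Rejection budget.** $10^6$ draws per value, then an error — a spec
  whose support misses the window entirely fails fast instead of
  looping forever.

What passing tests on these synthetic populations do *not* show: anything
about real social data. The generator produces isotropic, unimodal
populations with independent axes; real attribute surveys are correlated,
multimodal and bounded. The package's claims are about the model's
mathematics and its ensemble statistics under these stated conditions.

## Numerical and semantic choices

* **Merge threshold is strict** (`< CR`); ties at exactly CR do not
  merge. Merging is transitive within a pass (connected components), so
  the outcome is independent of pair enumeration order. Position
  tie-break at equal active masses: lowest agent id.
* **One merge pass per iteration**, after movement, plus one at time
  zero so coincident injected agents fuse before stepping. Mid-step
  fly-throughs (an agent crossing another's CR between the endpoints of
  one step) do not merge; only post-move positions count.
* **Sign decisions use the dot product directly** — no `acos`, no
  epsilon band around 90°; `dot == 0` gives exactly zero force.
* **Direction vector**: the unweighted difference $\mathbf{A}-\mathbf{B}$
  normalised by the *weighted* distance R, matching the model's formulas
  literally; for unit weights this is the ordinary unit vector.
* **Force sums** in the step record: "total attractive/repulsive force"
  is ambiguous between pairwise and per-agent-net sums. We sum the
  magnitudes of the *directed pairwise* forces (both directions of each
  communicating pair), classified by the sign of the scalar prefactor.
* **Moment of inertia** is not defined in the sources; we use
  $\sum_i M_i |r_i|^2$ about the origin with passive masses, and assert
  nothing against external values for it.
* **Adjacent-angle statistics for two survivors** pool both gaps (the
  minor and the reflex angle), exactly as for three or more, so the
  pooled mean is forced to 360/k and the SD measures the RMS deviation
  from symmetric placement. Folding to the minor angle alone would
  shrink the SD by $\sqrt{1-2/\pi}$ and shift the mean, and would not be
  comparable with the k ≥ 3 statistics.
* **Ensembles** use consecutive seeds from a base seed — reproducible,
  and every run in a sweep or grid has a distinct seed. Seed 0 on a
  single run means "draw a fresh seed and record it".

## Ensemble experiment sizes

The drivers take replicate counts as arguments, so larger ensembles
(thousands of runs per point, 100 per grid cell over a finer 21×21 grid)
are available behind the same interface. The package's own tests and the acceptance
script use: 100 runs per AIB for surviving-agent counts; 1000 runs at
AIB = 100 for the pooled final-state geometry (the pooled 12-sector SD is
dominated by counting statistics, so it is only comparable at matched
pooled counts); 100 runs at each of AIB 60–100 for the survivor-angle
spreads; an 11×11 grid (step 10) × 10 runs for the consensus map; and
8 far centers × 25 runs for the near-consensus rate. These sizes put all
stochastic checks within a few sampling standard errors of their
reference values.

## Known limitations

* The merge rule teleports the lighter member to the heavier one (up to
  CR away); with very large CR this visibly distorts trajectories, which
  is why CR defaults to 0.2 against typical inter-agent distances of
  tens of units.
* Equilibria with exactly orthogonal survivor pairs are knife-edge
  configurations; geometric presets can sit on them, and floating-point
  jitter decides which way they tip. Random initial conditions are never
  observed on them.
* The simulator is deterministic given a seed, but seeds are only
  meaningful within this implementation: RNG streams differ across
  implementations of the model, so per-seed layouts are not comparable
  with other software, only ensemble distributions are.
* Force computation is $O(n^2)$ per iteration; fine for the hundreds of
  agents the model targets, not for millions.

## A worked example

```{r, eval = FALSE}
library(fvmsim)
run <- fvm_run(standard_conditions(aib = 100, seed = 61))
run
metrics_snapshot(run$final_population, run$config_echo$model)

ens <- run_ensemble(standard_conditions(aib = 100), n_runs = 100,
                    base_seed = 1)
ens$summary$mean_final_agents     # around 2.3 survivors
median(ens$runs$mdcn)             # close to the AIB
median(ens$runs$centroid_drift)   # a few model units
```

Typical behaviour, all of it asserted quantitatively in the test suite:
small AIB leaves many scattered groups held by short-range attraction
(repulsive share of total force below 1%); large AIB funnels everyone
into two or three comparable groups that late repulsion drives to a
separation of about the AIB (repulsive share near 100% at the end); the
active-mass-weighted centroid barely moves; and pooled over many seeds
the final arrangements are angularly uniform.
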