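---
title: "Inferring gene-circuit parameters from single-cell trajectories: models and methods"
author: "CircuitCaliber"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring gene-circuit parameters from single-cell trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CircuitCaliber)
```

## The problem

Fluorescence time-lapse experiments on single cells report the copy number
of one or two tagged proteins at regular frame intervals, for days at a
time, over many cells.  Everything else in the circuit — mRNAs, dimers,
promoter occupancy, protein–promoter complexes — is invisible.
CircuitCaliber asks: given only those frame-sampled protein counts, how well
can different stochastic model families recover the circuit's underlying
rates, and at what computational price?

The package implements the full benchmark loop for two canonical circuits:

* **SGAA** — a single gene whose protein product dimerises and binds its own
  promoter to enhance transcription (positive autoregulation, bistable
  "noisy switch" expression);
* **TS** — a two-gene toggle switch in which each protein represses the
  other gene, producing two stable states (high A/low B and low A/high B).

Synthetic "experimental" data are generated from fine-grained reaction
schemes (mRNA, monomer, dimer, promoter states) with the exact Gillespie
stochastic simulation algorithm; three inference engines are then fitted to
the protein-count trajectories alone and judged by the effective rates they
recover.

## Data-generating circuits

The SGAA generator has nine reactions over species `a` (mRNA), `A`
(monomer), `A2` (dimer) and a two-state promoter: transcription at `g`
(basal) or `gStar` (activated), mRNA decay `d`, translation `p`, protein
decay `r`, dimerisation `fd`/`bd`, and dimer–promoter binding `fp`/`bp`.
Benchmark rates (s⁻¹): `d = 0.2`, `p = 0.02`, `fd = 5e-3`, `bd = 50`,
`fp = 6e-3`, `bp = 3e-5`, `g = 0.05`, `gStar = 0.5`, `r = 1e-3`.  These
produce switching between a low state near 5 copies and a high state near
50 copies on the scale of hours.

The TS generator uses one promoter with three mutually exclusive states:
basal (both genes transcribed at `g3`), A-bound (gene B repressed to
`g3Star`) and B-bound (gene A repressed), with `d3 = 0.5`, `p3 = 0.02`,
`f3 = 3.5e-6`, `b3 = 2e-5`, `g3 = 0.5`, `g3Star = 2.5e-3`, `r3 = 1e-3`
(all s⁻¹), a symmetric scheme in A and B.

Model-independent accuracy is scored on three **effective rates**: basal
production `peff`, activated/repressed production `peffStar`, and
per-capita degradation `reff`.  For the generators these follow from the
steady-state mRNA level: SGAA `peff = p·g/d = 5e-3`,
`peffStar = p·gStar/d = 50e-3`, `reff = r = 1e-3`; TS
`peff = p3·g3/d3 = 20e-3`, `peffStar = p3·g3Star/d3 = 0.1e-3`,
`reff = 1e-3`.

Simulation conventions the data format fixes:

* the frame interval defaults to `deltaT = 300` s — it is a required
  configuration field, recorded in every manifest, and all inference reads
  it from the data rather than assuming it;
* trajectories start at the basal promoter with all counts zero and a 12 h
  burn-in is discarded, removing the transient from stationary summaries;
* only tagged proteins are recorded (never mRNA or dimers), mimicking the
  fluorescence observable; frames are instantaneous samples;
* homodimerisation uses the exact-SSA combinatorial propensity
  `fd·N(N−1)/2`; a flag (`halveDimerisation = FALSE`) switches to
  `fd·N(N−1)` for users whose rate tables assume that convention;
* the promoter-bound dimer (SGAA) or monomer (TS) is sequestered: binding
  removes it from the free pool, unbinding restores it.

## The three inference engines

All three engines are scored through the same likelihood: pooled counts of
state transitions between frames `m` apart (non-overlapping windows),

  log L = Σ ω(i→j) · log P(i→j over m frames),

with `P` computed per model and maximised over that model's parameters by
Nelder–Mead simplex (derivative-free) on log-transformed rates, with five
seeded starts (method-of-moments centre, restarts from the incumbent, and
jittered centres).

**Detailed model (DM).**  A reduced scheme with an explicit promoter:
production of `A` at `g1` (basal) or `g1Star` (activated), decay `r1·N`,
and monomer binding/unbinding `f1·N` / `b1` with the bound monomer removed
from the free pool.  Its chemical master equation is truncated by Finite
State Projection — tracked counts `0..Nmax−1` plus one absorbing sink
aggregating everything beyond — and propagated by the matrix exponential
`exp(W·mΔt)`.  With `Nmax = 92` the SGAA DM matrix is 185×185; the TS DM
(two counts and two binary occupancy flags) reaches
`59·59·2·2 + 1 = 13925` states.  The promoter is hidden in the data, so
the observed-count transition probability marginalises it: the initial
promoter state is weighted by its quasi-stationary conditional given the
observed count, and final promoter states are summed.  At stationarity
this is the exact marginal transition probability, making the pooled
product a consistent composite likelihood.  Effective rates are read off
directly: `peff = g1`, `peffStar = g1Star`, `reff = r1` (and the `g4`
analogues for TS).

**Coarse-grain model (CGM).**  One species per gene; feedback enters only
through a Hill-type production propensity, `X(N) = g2 + g2Star·N²/(N²+K)`
for auto-activation and `X = g5 + g5Star/(N_other² + K)` for repression,
with per-capita decay.  The cooperativity is fixed at `n = 2` (the standard
choice for dimer-mediated regulation; an override exists but is excluded
from optimisation).  `K` spans orders of magnitude and is optimised in log
space.  Effective rates: SGAA `peff = g2`, `peffStar = g2 + g2Star`
(the saturated rate), `reff = r2`; TS `peff = g5 + g5Star/K` (no
repressor), `peffStar = g5` (full repression), `reff = r5`.

**Maximum Caliber (MaxCal).**  A top-down path-entropy model: within one
frame the micro-trajectory out of a state with `N` proteins is labelled by
`lAlpha` productions (capped at `M`) and `lA` survivors (0..N).
Maximising path entropy under constraints on mean production, mean
survival and the production–abundance correlation gives

  P(lAlpha, lA | N) ∝ C(N, lA) · exp(hAlpha·lAlpha + hA·lA + KA·lAlpha·lA),

with Lagrange multipliers `hAlpha, hA, KA` (a second coupling `KAbeta`
carries cross-gene repression in the toggle switch).  Degradation is
implicit in survival: there is no separate death multiplier.  The one-frame
transition matrix sums path probabilities over `lAlpha + lA = j`, and the
m-frame matrix is its m-th power (repeated squaring) — a matrix product
rather than a matrix exponential, which is the source of MaxCal's speed
advantage.  The cap `M` is an integer hyperparameter chosen by an
exhaustive likelihood grid (default `1:40`) with the multipliers
re-optimised at each `M` (warm-started from the previous grid point) and
ties broken toward smaller `M`.

MaxCal's effective rates come from the fitted chain itself: the stationary
law (dominant eigenvector of the one-frame matrix restricted to tracked
states, renormalised) is located; its low and high modes `NL`, `NH` are
found as strict local maxima (the two largest if more exist; a unimodal law
is reported as a failure, never silently patched); then
`peff = ⟨lAlpha⟩_{NL}/Δt`, `peffStar = ⟨lAlpha⟩_{NH}/Δt`, and
`r(N) = (N − ⟨lA⟩_N)/(N·Δt)` averaged under the stationary law over
`N ≥ 1` (r is undefined at N = 0, so the weights are renormalised there).
Conditional means are computed exactly from the path distribution, never
sampled.  Modes default to the model's stationary law; a flag switches to
the empirical histogram.

## Numerical choices

* **FSP truncation.**  Tracked counts are `0..Nmax−1` with the sink
  absorbing all counts ≥ `Nmax`; this convention reproduces the published
  matrix sizes (185, 93, 13925, 3482) for the quoted bounds.  When `Nmax`
  is not supplied it is chosen as `ceil(1.5 × max observed count)`, at
  least `max + 20` — comfortably above anything seen in the data.  The
  per-step sink leakage under the stationary law is monitored and a warning
  is raised beyond `1e-6` per step.
* **Matrix exponentials** use dense scaling-and-squaring
  (`Matrix::expm`); matrix powers use repeated squaring.  Propagator
  columns are checked to sum to 1 within `1e-8`.
* **Stationary laws** use a dense eigendecomposition below dimension 1500
  (with a spectral-gap check) and fall back to repeated squaring of the
  restricted propagator above it or when the gap degenerates.
* **Partition functions** (`Q`) are computed with a log-sum-exp shift;
  binomial degeneracies via log-factorial tables.
* **Likelihood floors.**  Model probabilities are floored at `1e-300`
  inside the log; the number of floored transitions is reported so that an
  impossible-transition misfit is visible rather than silent.
* **Optimiser box.**  Rates are kept inside `[1.5e-8, 20]` s⁻¹ (K up to
  `e^15`), multipliers inside `[-60, 60]`: far wider than any plausible
  fit, but preventing the simplex from requesting astronomically scaled
  matrix exponentials.

## Choice of the transition window m

The window enters the likelihood as the horizon of one transition factor.
`selectM()` implements the dwell-time heuristic: split pooled counts by
2-means, measure mean dwell (in frames) of the low and high clusters along
each trajectory, and take the geometric mean, clamped to
`[1, nFrames/10]`; degenerate (unimodal or constant) data fall back to
`m = 1` with a warning.  Multi-frame windows exist to protect the MaxCal path model from spurious
multi-protein jumps between consecutive frames, and `m` for MaxCal comes
from this heuristic.

For the exact-propagator models (DM and CGM) the package deliberately uses
a shorter window, `selectKineticM()`: one mean protein lifetime,
`m ≈ 1/(r̂·Δt)`.  The reason is identifiability: over windows much longer
than the protein lifetime the observed-count kernel approaches the
stationary law and constrains these models' rates only through ratios,
leaving the overall timescale nearly free — at the reduced benchmark scale
the dwell-window likelihood of either model can prefer parameter sets with
every rate scaled several-fold (and the maximiser then scatters widely
across replicates).  At one-lifetime windows the within-window relaxation
pins the timescale.  The lifetime estimate `r̂` comes from within-state
fluctuations: for a birth–death process at local equilibrium,
`Var(ΔN) = 2·N̄·(1 − e^{−rΔt})` over one frame, inverted for `r` and
pooled over the two occupancy clusters (a naive downward-flux estimate
underestimates `r` several-fold once `Δt` is a sizable fraction of the
lifetime, because births cancel most deaths within a frame).  Both window
choices are overridable (`m = ...`).

## The synthetic benchmark, and what passing it shows

`runBenchmark()` simulates replicate ensembles at the true rates, fits the
requested models per replicate, and reports mean ± sd of the effective
rates over replicates, in a table whose first row restates the truth.  The
package's routine problem size is 2 replicates × 20 trajectories × 48 h at
`Δt = 300` s (a few hundred dwell-scale windows per replicate), against the
full-scale study of 10 replicates × 100 trajectories × 7 days; tolerances
in the tests are set accordingly (±35% bands on DM and MaxCal rates, a
directional ≥1.5× check on the CGM's activated-rate overshoot).  Replicate
spread at this scale is substantial — a single replicate holds only a
couple of dozen switching events, which dominate the information about
production rates.

Two caveats on what the synthetic benchmark does and does not demonstrate.
First, the generator *is* a known stochastic reaction network: success here
shows the engines can see through mRNA bursts, dimerisation and promoter
hiding, not that they survive measurement noise — there is no fluorescence
noise layer, no proxy calibration, no photobleaching.  Second, parameter
recovery for each engine on data simulated from its *own* scheme (the
self-consistency tests) verifies estimator and optimiser correctness, not
model adequacy on real circuits.

In the self-consistency tests the generating parameters are chosen so that
every parameter is actually identifiable from the data: the CGM's `K` lies
inside the visited count range (a half-saturation point the data never
cross is unidentifiable in principle), and the MaxCal cap `M` is exercised
by net jumps that reach it (when production saturates far below the cap the
likelihood is flat in `M` and the parsimony tie-break simply returns the
smallest equivalent cap — a property of the model class, not an estimator
defect).

Timing of the basic likelihood operation (matrix exponential for DM/CGM,
matrix power for MaxCal) and of whole fits is recorded in every result as
an informational field; it is hardware-dependent and no accuracy statement
or test depends on it.  The full-scale TS detailed model (13925² matrix
exponentials) is far beyond routine test scale; its state space and
generator are constructed and verified at small bounds, and the dimension
arithmetic at the published bound.

## Known limitations

* The TS MaxCal transition-matrix builder enumerates the four path labels
  per state pair; its cost grows as `(M+1)²·(Nmax²/2)²` and is intended
  for moderate bounds, not the full 59×59 space with large `M`.
* The DM composite likelihood assumes stationarity when weighting the
  hidden promoter; strongly non-stationary recordings (no burn-in) would
  bias it.
* `selectM`'s 2-means split presumes two occupancy clusters; oscillatory
  or graded circuits need a user-supplied `m`.
* No tau-leaping or hybrid approximations: simulation is exact SSA only,
  by design.

## A worked 30-second example

```{r example, eval = FALSE}
library(CircuitCaliber)
cfg <- SimulationConfig(tEnd = 24 * 3600 + 12 * 3600, deltaT = 300,
                        nTrajectories = 4, burnIn = 12 * 3600, seed = 1)
trajs <- simulateSSA(buildSGAAGenerator(), cfg)
m <- selectM(trajs)
omega <- countTransitions(trajs, m)
fit <- maximizeLikelihood("maxcal", "sgaa", omega, trajectories = trajs,
                          Mgrid = 1:20)
fit
effectiveRates(fit)
```

Larger, slower runs (the full reduced-scale benchmark) go through
`runBenchmark()`; `scripts/acceptance.R` in the source repository runs it
end to end and writes the headline numbers as JSON.
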