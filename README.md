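# CircuitCaliber

Benchmarking stochastic-inference engines for small gene circuits from
single-cell protein-count trajectories.

Fluorescence time-lapse experiments record the copy number of one or two
tagged proteins every few minutes, for days, over many cells — and nothing
else.  mRNAs, dimers and promoter occupancy stay invisible.  CircuitCaliber
implements, end to end, the standard way of asking how much circuit detail
can be recovered from such data: simulate a fully specified circuit exactly,
hand the inference engines only what an experiment would see, and score
what they recover.

Two circuits are built in:

* **SGAA** — single-gene auto-activation: the protein dimerises and the
  dimer activates its own promoter (`α + A2 ⇌ α*`), producing bistable,
  switch-like expression;
* **TS** — a symmetric two-gene toggle switch with mutual repression
  through monomer–promoter binding.

Three inference engines share one likelihood — pooled m-frame transition
counts, `log L = Σ ω(i→j) log P(i→j)` — and differ in how they compute
`P`:

| engine | state space | P(i→j) | feedback enters via |
|---|---|---|---|
| `dm` (detailed) | counts × promoter states + sink | `exp(W·mΔt)` (FSP matrix exponential) | explicit binding reactions |
| `cgm` (coarse-grain) | counts + sink | `exp(W·mΔt)` | Hill propensity `g + g*·N²/(N²+K)` |
| `maxcal` (Maximum Caliber) | counts + sink | m-th matrix power of a one-frame path-probability matrix | production–abundance coupling `KA` |

The Maximum Caliber engine is a top-down path-entropy model: per frame,
`lα` productions (≤ M) and `lA` survivors follow
`P(lα, lA | N) ∝ C(N, lA)·exp(hα·lα + hA·lA + KA·lα·lA)`, with the
Lagrange multipliers fitted by likelihood maximisation and the cap `M`
chosen on an exhaustive grid.  Accuracy is compared on effective rates
(`peff`, `peff*`, `reff`); for the SGAA generator the truth is
`peff = p·g/d = 5×10⁻³ s⁻¹`, `peff* = p·g*/d = 50×10⁻³ s⁻¹`,
`reff = r = 10⁻³ s⁻¹`.

## A worked example

```r
library(CircuitCaliber)

cfg    <- SimulationConfig(tEnd = 24*3600 + 12*3600, deltaT = 300,
                           nTrajectories = 4, burnIn = 12*3600, seed = 1)
trajs  <- simulateSSA(buildSGAAGenerator(), cfg)   # exact SSA, A only
omega  <- countTransitions(trajs, selectM(trajs))
fit    <- maximizeLikelihood("maxcal", "sgaa", omega,
                             trajectories = trajs, Mgrid = 1:20)
fit
```

```
InferenceResult [maxcal/sgaa] logLik = -117.142, converged = TRUE
  params:  hAlpha=-0.6392, hA=0.6948, KA=0.03747, M=13
  effective rates (x1e-3 / s): peff=4.41 peff*=40.58 reff=0.92
```

Read: the fitted multipliers say production is suppressed (`hAlpha < 0`)
but strongly coupled to abundance (`KA > 0` — the auto-activation the model
discovered), and the extracted rates land near the generator's truth of
(5, 50, 1)×10⁻³ s⁻¹ even from this very small data set.  The full
benchmark, with replicate error bars and all three engines,

```r
cfg <- SimulationConfig(tEnd = 60*3600, deltaT = 300, nTrajectories = 20,
                        nReplicates = 2, burnIn = 12*3600, seed = 1)
renderReport(runBenchmark("sgaa", cfg, seed = 2))
```

```
Method   peff (1e-3/s)    peff* (1e-3/s)   reff (1e-3/s)
True     5                50               1
DM       5.4 ± 0.39       52 ± 3.4         1.1 ± 0.072
CGM      4.8 ± 0.21       96 ± 2           1.2 ± 0.068
MAXCAL   5.2 ± 1.5        44 ± 11          1 ± 0.24
```

shows the characteristic finding: the detailed and MaxCal engines recover
the rates, while the minimal Hill coarse-grain model overshoots the
activated production rate by roughly a factor of two — it compensates for
the sharp dimer-mediated switch with a larger amplitude.

A thin CLI over the same functions lives in `inst/cli/caliber.R`
(`simulate`, `infer`, `benchmark`, `report` subcommands; see the file
header), with YAML configs as in `inst/extdata/sgaa_benchmark.yaml`.

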