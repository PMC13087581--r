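# plategrowth

Growth-curve analysis for liquid-culture microbial assays measured on plate
readers — nephelometric (Relative Nephelometric Units, RNU) or
spectrophotometric (OD600) — built for yeast complementation experiments in
which heterologous transporter constructs rescue growth of an uptake-deficient
strain on a selective nitrogen source. The package quantifies *when* a culture
grows fastest, not just whether it grows: the readout of interest is the time
of maximum slope of the growth curve, which reflects the length of the lag
phase and lets otherwise similar constructs be distinguished statistically.

## What it computes

Signal traces are modelled as logistic population growth under limited
resources:

    N(t) = K / (1 + ((K - N(0)) / N(0)) * exp(-r t))

with carrying capacity `K`, initial population `N(0)` and growth rate `r`
(per hour), fitted by least squares with all three parameters constrained
positive. Initial values are taken from the data — `K` from the curve
maximum, `N(0)` from the minimum, and `r` by solving the logistic form at the
empirical maximum-slope time μ: `r = log((K − N(0)) / N(0)) / μ`.

From the fit the package derives, per biological replicate:

- **maximum-slope time** `μ = log((K − N0)/N0) / r` — the inflection, where
  the population is `K/2` and growth is fastest;
- **lag time** by the classical tangent construction,
  `t_lag = μ − 2/r + 4 N0 / (r K)`;
- **maximum growth rate** `r K / 4` (the slope at the inflection).

Before fitting, each well trace passes through the correction chain used for
plate assays: blank subtraction (per-medium mean of non-inoculated wells),
subtraction of the mean background growth of the empty-vector negative
control (test medium only), clamping of all values before the curve minimum,
rebasing of the initial population to 1 unit, Savitzky–Golay smoothing
(order 2, window covering 10 % of the samples), and technical-replicate
averaging. Groups are compared with a Mann–Whitney *U* test whose two-sided
p-value is exact (full rank-subset null) at pipeline sample sizes.

A plate simulator (`simulatePlate()`) generates synthetic assays with
per-well ground truth — replicate hierarchy (3 biological × 3 technical),
blank baselines, background-growth controls, and the nephelometric
peak-then-decline scattering artifact — so the entire pipeline can be
validated without laboratory data.

## Worked example

```r
library(plategrowth)

cfg <- runConfig(simConfig = simulationConfig(seed = 7),
                 outDir = "run-out", seed = 7)
res <- runPipeline(cfg)
```

This simulates the default nephelometric assay — two constructs (`AtLHT1`,
`PtrLHT1.2`) with true inflection times 65 h and 72 h, carrying capacity
1000 RNU, 2 % measurement noise, a ccdB empty-vector background control and
triplicate blanks, sampled every 10 minutes for 180 h — then preprocesses,
fits and compares. The per-replicate metrics it prints:

```
                     curve      K      r  mu_h lag_h
    AtLHT1/citrulline/bio1 1082.8 0.1108 62.35 44.34
    AtLHT1/citrulline/bio2 1076.4 0.1133 62.23 44.61
    AtLHT1/citrulline/bio3 1072.5 0.1136 62.94 45.36
 PtrLHT1.2/citrulline/bio1 1083.8 0.1163 67.19 50.00
 PtrLHT1.2/citrulline/bio2 1091.7 0.1182 65.15 48.25
 PtrLHT1.2/citrulline/bio3 1085.1 0.1144 67.88 50.41

GroupComparison [max_slope_time] AtLHT1 (n=3) vs PtrLHT1.2 (n=3):
  U = 0, p = 0.1 (exact)
```

Every `AtLHT1` replicate reaches maximum growth ~5 h earlier than every
`PtrLHT1.2` replicate (the simulated offset, slightly compressed by the
fit-through handling of the scattering peak), giving complete separation:
`U = 0` with the exact two-sided p of 0.1, the smallest attainable at
3 vs 3. Outputs land in `run-out/`: `metrics.csv`, `comparisons.csv`, the
simulated inputs, and `run_manifest.txt` (config hash, seed, stage
provenance); reruns with the same config and seed are byte-identical.

A command-line front end with `simulate`, `analyze` and `compare`
subcommands is installed at `inst/scripts/plategrowth.R`.

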