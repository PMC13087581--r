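---
title: "Methods: logistic growth-curve analysis for plate-reader assays"
author: "plategrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: logistic growth-curve analysis for plate-reader assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plategrowth)
```

## The measurement problem

Yeast complementation assays read out transporter function as growth on a
selective nitrogen source: an uptake-deficient strain grows on citrulline
medium only if the heterologous transporter it carries can import the amino
acid. On solid media the readout is binary. In liquid culture a plate reader
records a full growth trajectory per well — light scattering in Relative
Nephelometric Units (RNU, sampled every 10 minutes for a week) or manual
OD600 (about twice daily) — and the *shape* of that trajectory becomes
quantitative: two constructs that reach the same final density can differ
reproducibly in when they reach their fastest growth. `plategrowth` extracts
that timing and tests it between construct groups.

## Model

Each preprocessed curve is modelled as logistic population growth under
limited resources,

$$N(t) = \frac{K}{1 + \frac{K - N_0}{N_0}\, e^{-r t}},$$

with carrying capacity $K$ (signal units), initial population $N_0 = N(0)$,
and growth rate $r$ (h$^{-1}$), all constrained positive. The quantities of
interest are functions of the fit:

* **maximum-slope time** $\mu = \log\!\big((K - N_0)/N_0\big)/r$, the
  inflection, where $N = K/2$ and $dN/dt$ is maximal;
* **maximum growth rate** $rK/4$, the slope at the inflection;
* **lag time** by the tangent construction: the tangent at the inflection,
  $y = K/2 + (rK/4)(t - \mu)$, intersected with $y = N_0$ gives
  $t_{\mathrm{lag}} = \mu - 2/r + 4N_0/(rK)$, clipped below at 0. No formula
  for lag time is universal; the tangent-at-inflection construction is
  classical growth-curve practice and is fully determined by $(K, N_0, r)$,
  which keeps it consistent with the fitted model. It always satisfies
  $t_{\mathrm{lag}} < \mu$ when the inflection is interior.

The model assumes a single exponential-to-saturation transition: no
diauxie, no death phase. When $K \le 2N_0$ the inflection lies at or before
$t = 0$; over observable time the slope is then maximal at $t = 0$, and the
package reports $\mu = 0$ with a boundary flag rather than a negative time.

## Preprocessing chain

Applied per technical-replicate well, in this order:

1. **Blank correction** — subtract, per time point, the mean of the
   non-inoculated blank wells of the same medium. Negative values are
   retained; the next two steps subsume their handling. The mean of the
   triplicate blanks (rather than a single matched well) is used because it
   halves the blank's noise contribution.
2. **Negative-control normalization** (test medium only) — subtract the
   per-time mean of the blank-corrected empty-vector (ccdB) traces, removing
   background growth that does not reflect transporter activity. Applying it
   to a non-test-medium trace is a warning no-op: on control media every
   construct grows, and the subtraction would remove signal, not background.
   The control construct's own test-medium wells are consumed as the
   reference and not analyzed further (their normalized mean is identically
   zero).
3. **Pre-minimum clamping** — all values before the *first* occurrence of
   the global minimum are set to that minimum. Early nephelometric readings
   can drift downward while cells settle; clamping removes the spurious
   negative slope. First occurrence is used so that values between tied
   minima are untouched.
4. **Rebasing** — an additive shift puts the initial population at exactly
   1 unit. A shift (not a division) preserves all differences, and hence the
   empirical maximum-slope time, and behaves sanely when blank-corrected
   values sit near zero.
5. **Savitzky–Golay smoothing** — order 2, window the smallest odd integer
   $\ge \max(5, \mathrm{round}(0.10\,n))$ (10 % of the samples; 101 points
   for a 7-day 10-minute trace, the floor of 5 engaging for sparse OD600
   series of ~15 points). An order-2 filter reproduces any quadratic
   exactly, preserving curvature through the inflection. Terminal points are
   fitted within the one-sided end windows; nothing is padded or reflected,
   so no data is fabricated at the boundaries where lag and plateau are
   read. The filter assumes a uniform grid; steps deviating more than 10 %
   from the median step are refused (plate readers jitter by seconds
   against a 10-minute cadence, which passes; merged runs with gaps do not).
6. **Technical-replicate averaging** — pointwise mean into one curve per
   (construct, medium, biological replicate). Smoothing before averaging
   follows the assay's processing order; since the filter is linear the two
   orders differ only through the per-well clamp/rebase offsets.

## Fitting

Bounded least squares (Levenberg–Marquardt, `minpack.lm`), lower bound
$10^{-12}$ on each parameter — the smallest intervention that realises the
positivity constraint without reparameterizing the stated problem. Relative
function tolerance $10^{-10}$, at most $10^4$ residual evaluations; the
convergence flag is recorded per curve and never silently discarded.

Initialization is data-driven: $K_0$ and $N_{0,0}$ are the curve maximum and
minimum, and $r_0 = \log((K_0 - N_{0,0})/N_{0,0})/\hat\mu$, where $\hat\mu$
is the empirical maximum-slope time (midpoint of the steepest
forward-difference interval, earliest on ties, computed on the smoothed
curve since initialization follows smoothing in the chain). When the log
argument is $\le 1$ or $\hat\mu \le 0$ the expression is undefined or
non-positive and $r_0$ falls back to $1/T$ ($T$ the time span): any positive
rate of order $1/T$ lets the optimizer proceed. A flat curve (max = min) has
no growth signal and is an error, not a fit.

## Group comparison

The Mann–Whitney $U$ test compares a metric (default: maximum-slope time)
between two construct groups. Midranks handle ties;
$U_a = R_a - n_a(n_a+1)/2$ and the reported statistic is
$U = \min(U_a, U_b)$, the classical-table convention (the other direction is
$n_a n_b - U$). The two-sided p doubles the exact lower-tail probability
$P(U \le u)$ under the permutation null, capped at 1 — computed from the
full rank-subset null distribution whenever $n_a n_b \le 400$ and the data
are tie-free (instant at pipeline scales of ≤ 9 units per group), else by
normal approximation with tie and continuity corrections. If all values are
identical the comparison is degenerate with $p = 1$.

The statistical unit defaults to the biological replicate — technical
replicates are pseudo-replicates of the same culture and are averaged
upstream. Box plots in this assay family sometimes suggest more units than
biological replicates; for that reason `unit = "tech"` is exposed, which
fits each technical replicate separately, but inference from it treats
correlated wells as independent and is not the default.

Note the granularity this implies: at 3 vs 3 biological replicates the
smallest attainable two-sided exact p is $2/\binom{6}{3} = 0.1$ —
complete separation is evidence of an effect but can never cross 0.05.
Detecting a difference at conventional thresholds requires pooling
biological replicates across runs or more replicates per run.

## The simulator

`simulatePlate()` generates the statistical structure the analysis assumes,
with exported per-well ground truth. Per group the user states
$(K, r, \mu)$; the well's $N_0$ is solved exactly from the closed form,
$N_0 = K/(1 + e^{r\mu})$, so the true inflection time is an input, not a
by-product. Defaults are the nephelometric assay design: 180 h at 10-minute
cadence (1081 points), 3 biological × 3 technical replicates per construct,
triplicate blanks, two constructs with $K = 1000$ RNU, $r = 0.1$ h$^{-1}$
and $\mu = 65$ vs $72$ h, a ccdB-like background group
($K_c = 50$, $r_c = 0.05$ h$^{-1}$, unit inoculum — slow, shallow growth an
order of magnitude below the transporters), blank baseline 10 RNU, and
Gaussian noise with sd 2 % of the group's $K$ (blank wells: 2 % of the
baseline, instrument noise at dark-signal level). The spectrophotometric
mode switches to 12-hour sampling (~15 points, twice daily), 5 % noise for
manual cuvette handling, and no scattering artifact.

Biological replicates differ through the growth rate: each (group, bio)
draws $r_{\mathrm{bio}} = r\,e^{\varepsilon}$,
$\varepsilon \sim \mathcal N(0, 0.03^2)$ — a 3 % coefficient of variation,
a realistic day-to-day spread between independently grown cultures — and
the per-replicate true $\mu$ is recomputed from the closed form, so ground
truth stays exact. Putting the replicate effect on $r$ rather than $K$ keeps
the inflection time, the assay's readout, the quantity that varies.

**Peak artifact.** Dense nephelometric cultures show a peak in scattering
followed by a decline and a plateau (multiple scattering transiently
amplifies the signal). The simulator reproduces the shape with a
multiplicative, density-gated factor on the population signal:

$$1 + a\,\frac{N}{K}\,e^{-\delta\,\max(0,\, t - t_{\mathrm{onset}})},$$

with $t_{\mathrm{onset}}$ the first time $N \ge c\,K$. Defaults $a = 0.3$,
$c = 0.5$ (amplification engages at half-saturation density, i.e. from the
inflection), $\delta = 0.02$ h$^{-1}$. The decay constant is deliberately
slow relative to the growth timescale: relaxation much faster than the
rise to saturation would erase the peak before the density is high enough
to express it. With the defaults the noiseless trace peaks roughly 10 %
above its end value and relaxes toward the plateau within the run — the
qualitative peak–decline–plateau shape with three interpretable knobs, not
a mechanistic optics model. The magnitude of the real decline cannot be
fixed without instrument data; the defaults are plausible placeholders.

The simulator does **not** emulate: evaporation or drift trends (a linear
blank-drift knob exists for robustness testing but defaults to 0), well
position effects, cross-well contamination, autocorrelated noise, diauxic
shifts, or a death phase. Passing tests therefore demonstrate correctness
of the pipeline under the stated generative model, not robustness to every
failure mode of real plates.

## Fitting through the peak

How a monotone logistic should treat the post-peak decline is genuinely
open: truncating at the peak discards the plateau that anchors $K$, while
fitting through treats the artifact as symmetric noise around saturation.
The package fits through by default (truncation is easy to apply upstream
by subsetting the trace). Fitting through biases $K$ slightly upward and
pulls the apparent inflection a few percent earlier — the validation suite
measures this bias on simulated plates (it stays under 10 % of $\mu$ at
artifact amplitude 0.3) — but it uses every observation and never
hand-picks a truncation point. Because the artifact acts on both groups of
a comparison alike, rank-based group differences are essentially
unaffected.

## Numerical and validation choices

* Time is elapsed hours from each well's first measurement; every
  computation depends only on elapsed time.
* Exact Mann–Whitney nulls are cached per $(n_a, n_b)$; the null is built by
  the rank-sum counting recursion, mathematically identical to enumerating
  all $\binom{n_a+n_b}{n_a}$ subsets.
* Validation problem sizes: noiseless closed-form recovery and noise
  recovery use full 1081-point plates; type-I calibration uses $10^4$
  null simulations at $n = 6$ per group; offset discrimination uses 100
  simulated runs of the default two-construct plate. These sizes make the
  whole validation suite run in about a minute while keeping Monte Carlo
  error well inside the asserted bands.
* Outputs are written without timestamps; a run manifest records the config
  hash, seed and per-curve stage provenance, so identical configs reproduce
  byte-identical results.

## Known limitations

* One logistic per curve: no Gompertz/Baranyi/Richards alternatives, no
  model selection, no area-under-curve or doubling-time outputs.
* The exact test's discreteness at pipeline sample sizes (see above) caps
  attainable significance; the package reports the exact p rather than
  pretending continuity.
* Cross-run gain differences of nephelometers (laser intensity settings)
  are not rescaled; comparisons should stay within one run, or rely on
  rank statistics as done here.
* Spectrophotometric series of ~15 points sit at the smoother's floor
  window of 5; smoothing there is mild, and the logistic fit carries most
  of the denoising.
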