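---
title: "Quantifying lymphocyte production and loss from heavy-water labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lymphocyte production and loss from heavy-water labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lymphkin)
```

## The measurement problem

Drinking deuterated water (²H₂O) labels the DNA of every cell produced
while the label is present. Sorting a lymphocyte subset at successive time
points and measuring the ²H fraction of its DNA therefore traces how fast
that subset is replenished. `lymphkin` implements the full quantitative
chain for such a study in humans — here, patients roughly half a year to a
year after autologous stem-cell transplantation, labeled for six weeks,
compared with healthy controls labeled for nine — from raw enrichment
series to cohort-level fold changes in production and loss rates.

## Model

**Body water.** Label availability is the deuterium fraction in body water,

$$U(t) = f\,(1 - e^{-\delta t}) + \beta\, e^{-\delta t}, \quad t \le \tau,
\qquad U(t) = U(\tau)\, e^{-\delta (t - \tau)}, \quad t > \tau,$$

where $\beta$ is the enrichment reached by the ramp-up dose on day 0, $f$
the plateau maintained by daily dosing, $\delta$ (per day) the body-water
turnover rate and $\tau$ the end of label intake (42 d for patients, 63 d
for controls; fixed by protocol, never estimated). The functional form is
the standard one for a ramp-up-plus-maintenance protocol; it is continuous
at $\tau$ by construction.

**Label fraction of a subset.** For a kinetically homogeneous population
with per-cell production rate $p$, the fraction of labeled DNA $l = L/X$
obeys $dl/dt = p\,(c\,U(t) - l)$ with $l(0)=0$, where $c$ is the
amplification factor mapping body-water enrichment to the maximal
attainable DNA enrichment. Two facts shape the whole pipeline:

* the loss rate $d$ cancels out of the fraction (quotient rule), so
  enrichment identifies production only;
* for naive cells fed by a source $\sigma$ (thymus, bone marrow) plus
  division $p_N$, the same equation holds with the combined per-cell rate
  $p = \sigma/N + p_N$, under the assumption that this combined rate is
  constant over the study window. Both facts are enforced by oracle tests
  against numerical integration of the underlying two-compartment systems.

The package evaluates $l(t)$ in closed form, piecewise over the labeling
and de-labeling phases, with the $p = \delta$ singularity handled by the
analytic limit ($t e^{-pt}$ term) rather than a numerical guard.

**Kinetic heterogeneity.** A subset may comprise up to two subpopulations,
fractions $\alpha_i$ (summing to 1) with rates $p_i$; the observed curve is
$\sum_i \alpha_i\, l(t; p_i)$, components stored in decreasing rate order
to remove label-switching ambiguity. The reported quantity is the average
per-cell production rate $p = \sum_i \alpha_i p_i$.

**Scaling.** Granulocytes turn over fast enough to reach the maximal
attainable enrichment; the fitted granulocyte curve's maximum $M$ over the
observation window defines 100% incorporation, and subset enrichment is
divided by it. $M$ is taken over the sampled window, not as an analytic
global maximum, mirroring its definition as a data-window quantity.

**Cell numbers.** Because the cohort is not at steady state, normalized
subset counts (leukocyte regression line × subset fraction) are modeled as
$X(t) = X_0 e^{(p - d)t}$; combining the enrichment-identified $p$ with the
count-identified net slope $r = p - d$ yields the loss rate $d = p - r$,
bounded below at 0 (clipping is flagged, never silent).

## Estimation

All fits are maximum likelihood with independent homoscedastic Gaussian
errors per data stream on variance-stabilized scales: arcsin-√ for
enrichment fractions, log₁₀ for counts. Stream variances are profiled
analytically, so minimizing
$\tfrac{n_e}{2}\log(\mathrm{RSS}_e/n_e) + \tfrac{n_c}{2}\log(\mathrm{RSS}_c/n_c)$
is exact ML and supplies the relative stream weighting without tuning
constants. Two numerical choices matter:

* **Variance floor.** Each stream's profiled variance is floored at
  $10^{-16}$. Without it, noise-free (or bootstrap-degenerate) data let one
  stream's log-variance diverge and dominate the joint objective.
* **Conditional linearity.** Given the rates, the count model is linear in
  $(\log_{10} X_0,\, p - d)$, so $d$ and $X_0$ are profiled out by ordinary
  least squares at every objective evaluation (with $d$ pinned to
  $[0, 2]$/d when the unconstrained solution leaves the box). This removes
  a zero-residual degeneracy that otherwise traps quasi-Newton optimizers
  on noise-free data, and cuts the search space to the 1 (one component) or
  3 (two components) enrichment parameters.

The search uses 20 Latin-hypercube multi-starts over log-spaced rates
$p \in [10^{-5}, 2]$/d (plus a small structured grid and, for the
two-component fit, warm starts from the one-component optimum so the
nested model can never genuinely fit worse), a short coarse pass from every
start, quasi-Newton polishing of the best candidates with
finite-difference steps scaled to the box, and a simplex/quasi-Newton
alternation to escape the curved rate–amplitude ridges typical of
multi-exponential models. Fits are deterministic given their seed.

**Model selection.** One versus two subpopulations is decided by the
extra-sum-of-squares F-test on the enrichment RSS (two extra parameters,
level 0.05) — the criterion behind "significantly better described by two
subpopulations". If the two-component optimum is worse than the
one-component one, the optimizer has failed and one component is kept with
a warning.

**Bootstrap.** 95% confidence intervals come from a residual bootstrap:
per-stream residuals on the transformed scales, rescaled for their
underdispersion (per-point leverage factors $1/\sqrt{1-h_{ii}}$ from the
linearized model for subset fits; the global $\sqrt{n/(n-k)}$ correction
for body-water fits), symmetrized (each residual enters the pool with both
signs — the error model is symmetric Gaussian, and at ~10 residuals per
stream the raw pool's accidental skew demonstrably shifts the percentile
endpoints and costs coverage), resampled independently
with replacement, data rebuilt, model refit from the point estimate, and
2.5/97.5 percentiles taken per parameter. The selected number of
components is held fixed across replicates: the interval describes the
reported model, not a model average. Intervals are deterministic given the
seed, and are widened (rarely, and minimally) to bracket the point
estimate so the percentile contract always holds.

## Excision circles

KREC arithmetic uses the two printed assay formulas: replication history
$(Ct_{sj} - Ct_{cj})_{sample} - (Ct_{sj} - Ct_{cj})_{U698}$, and
coding-joint frequency
$2^{(Ct_{alb} - Ct_{cj})_{sample} - (Ct_{alb} - Ct_{cj})_{U698}} \times 100\%$.
Negative division counts and fractions above 100% are flagged, never
clipped — assay noise stays visible. TREC content is copies per cell
equivalent, with DNA converted at 6.6 pg per diploid genome (the
literature constant; exposed as an argument because the original
conversion is not printed).

## The synthetic cohort

No raw data from the study are redistributable, so the package ships a
generator whose defaults *are* the study design: 42-day labeling for
patients, 63 for controls, four blood draws during labeling and six after,
the last at about one year, urine through the first 13 weeks. Defaults
that the protocol fixes are derived from it (β ≈ 0.007 from the 7.5 ml/kg
ramp-up dose, f ≈ 0.015 from the 1.25 ml/kg/day maintenance dose at a
body-water turnover of δ = 0.07/d); the rest are set once to values a
kineticist would call typical: granulocyte turnover 0.3/d, amplification
factor c = 4, healthy-control subset rates in the range reported for
adult humans (naive T ≈ 0.05–0.06%/day, memory T ≈ 0.6%/day, B subsets
0.5–0.8%/day), controls at steady state ($d = p$, flat counts), and
patients carrying the production-rate folds 6/3/8/4 (naive/memory CD4,
naive/memory CD8) and 2/3.5/5 (naive, switched, IgM⁺ memory B), with loss
folds 3–5 and 9.5 for naive CD8.

Noise is injected exactly where the fitter assumes it: Gaussian sd 0.02 on
the arcsin-√ of the *scaled* subset enrichment (and of raw urine and
granulocyte enrichment), sd 0.05 log₁₀ units on counts. A misspecified
mode (additive raw-scale noise) exists for robustness checks. Between
individuals, rates and inclusion counts get lognormal jitter (sd 0.15),
while the net growth rate is perturbed in proportion to turnover (sd
0.2 p) and the loss rate rederived as $d = p - r$: jittering $p$ and $d$
independently would imply hundred-fold count changes over the follow-up
year, which no real cohort shows and which would contradict the
steady-state control design.

The generator also supports an explicit-source mode (σ, p_div, N₀), solved
by Runge–Kutta integration of the source-plus-division system, so the
σ/N + p_N reduction is testable against an independent route rather than
by construction.

What the generator does **not** emulate: plate and batch effects in GC/MS
or qPCR, missing visits, time-varying production rates during
reconstitution, blood–tissue exchange, and measurement-model
misspecification beyond the optional raw-noise mode. A green
parameter-recovery test therefore certifies the estimator under its own
assumptions, not robustness to these phenomena.

## Known limitations

* **Fast-component identifiability.** With weekly-at-best sampling, a
  subpopulation turning over at ≳ 0.2/day saturates between draws; its
  rate is then only bounded below, and the likelihood is nearly flat along
  the $\alpha_1$–$p_1$ ridge. The ML point estimate of the *average*
  production rate of such subsets is unstable per individual (simulations
  in the test suite show the wrong-ridge optima genuinely beat the truth
  in likelihood). Group medians damp but do not remove this; bootstrap
  intervals for these subsets are honest about it by being wide.
* **Tiny loss rates.** A healthy naive-T loss rate of ~5×10⁻⁴/d is below
  the precision of a count-slope estimate from ten draws at 0.05 log₁₀
  noise (slope s.e. ≈ 4×10⁻⁴/d), so control loss rates — and hence
  patient/control loss-rate folds with small denominators — carry large
  relative uncertainty by design.
* Production estimates inherit the body-water and granulocyte fit
  multiplicatively through $c$ and $f$; at the default urine schedule the
  plateau $f$ carries ~7% median error at transformed-scale noise 0.01.
* Two kinetic components at most; no hierarchical pooling across
  individuals; no compartmental blood–tissue exchange.
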