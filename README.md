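# lymphkin

Quantifies **production and loss rates of human lymphocyte subsets from in
vivo heavy-water (²H₂O) labeling**, for studies that compare a perturbed
cohort — here, patients half a year to a year after autologous stem-cell
transplantation — with healthy controls. It is aimed at immunologists and
biostatisticians running stable-isotope labeling studies who need the full
chain from raw enrichment tables to cohort-level fold changes, with
uncertainty, in reproducible form.

## The model

Label availability in body water follows

```
U(t) = f (1 − e^(−δt)) + β e^(−δt)     t ≤ τ   (labeling)
U(t) = U(τ) e^(−δ(t−τ))                t > τ   (washout)
```

with ramp-up enrichment β, plateau f, turnover δ and labeling end τ (42 d
patients, 63 d controls). The labeled-DNA fraction of a subset with
per-cell production rate p and amplification factor c solves
`dl/dt = p (c U(t) − l)`, evaluated in closed form; kinetic heterogeneity
is a two-component mixture `Σ αᵢ l(t; pᵢ)` with average production rate
`p = Σ αᵢ pᵢ`. Enrichment is scaled to the fitted granulocyte maximum M
(granulocytes reach full incorporation). Because the label *fraction* is
blind to the loss rate, cell numbers are modeled alongside as
`X(t) = X₀ e^((p−d)t)` on normalized counts (leukocyte trend × subset
fraction), giving `d = p − r`. Fits are maximum likelihood on arcsin-√
(enrichment) and log₁₀ (counts) scales with stream variances profiled; one
vs two subpopulations is an extra-sum-of-squares F-test; 95% CIs come from
a residual bootstrap. TREC content and the two KREC formulas (replication
history and coding-joint frequency) cover the excision-circle layer, and a
synthetic-cohort generator with known ground truth stands in for the raw
study data. See `vignettes/lymphkin-methods.Rmd` for the full account.

## Worked example

One synthetic transplant patient, fitted end to end:

```r
library(lymphkin)

cfg     <- paper_like_config("patient", subsets = "naive_cd4")
dataset <- generate_individual(cfg, seed = 1)

urine <- as_enrichment_series(dataset$enrichment, "ID1", "urine")
gran  <- as_enrichment_series(dataset$enrichment, "ID1", "granulocytes")
bwfit <- fit_body_water_and_granulocytes(urine, gran, tau = 42)

scaled <- granulocyte_scale(bwfit,
            as_enrichment_series(dataset$enrichment, "ID1", "naive_cd4"))
cnt <- subset(dataset$counts, subset == "naive_cd4")
cs  <- normalize_counts(count_series("ID1", cnt$time_days,
         cnt$leukocytes_per_ml,
         subset_counts = data.frame(time_days = cnt$time_days,
                                    subset = "naive_cd4",
                                    count = cnt$subset_count_per_ml)))
fit <- fit_subset_auto(scaled, cs$normalized[, c("time_days", "count")],
                       bwfit$params$bw, bwfit$params$c_amp, bwfit$params$M)
fit <- bootstrap_ci(fit, n_boot = 200, seed = 1)
print(fit)
```

```
lymphkin fit (subset), 1 kinetic component(s)
  p        0.0038754  [0.0035781, 0.0041603]
  p1       0.0038754  [0.0035781, 0.0041603]
  alpha1   1  [1, 1]
  d        0.0024746  [0.0015324, 0.003401]
  r        0.0014008  [0.00056884, 0.0022525]
  X0       60191  [51600, 68908]
  log-likelihood: 41.82
```

Read: this naive-CD4 pool gains ~0.39% of its size in new cells per day
(truth for this simulated individual: 0.36%/day) and loses ~0.25%/day
(truth 0.24%), so it is growing at ~0.14%/day from an inclusion count of
~60,000 cells/ml; brackets are 95% residual-bootstrap intervals.

The same analysis runs as a pipeline over a whole cohort:

```sh
Rscript inst/cli/lymphkin.R all --out run1 --seed 11
# run1/data/      simulated cohort CSVs + ground truth
# run1/fits/      fits.csv (one row per parameter), runlog.json
# run1/report/    report.csv + report.md: per-subset medians, patient/control
#                 fold changes, exact Mann-Whitney p-values
```

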