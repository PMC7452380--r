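# circaluc

Period estimation and temperature-compensation analysis for circadian
bioluminescence recordings.

## What problem this solves

Clock-gene–luciferase fusions (*ptim-TIM-luc*, *XLG-luc*, *tim-luc*,
*plo*, *8.0-luc*, ...) let chronobiologists watch a tissue's circadian
clock as a photon-count time series: entrain the preparation to
light:dark cycles, release it into constant darkness (DD), and record
counts per second for days in a plate reader. Turning those traces into
biology requires a chain of small, error-prone steps — trimming the
entrainment segment, detrending the substrate-depletion decay, fitting a
damped cosine to estimate the free-running period τ, discarding
untrustworthy fits, aggregating per genotype × tissue × temperature, and
asking the temperature-compensation question. `circaluc` packages that
chain for R, with S4 data containers, a config-driven pipeline, and a
synthetic-cohort generator so the whole machinery is testable end to end
without any raw recordings.

## The core quantities

* **Damped-cosine fit** of the detrended DD signal,
  `r(t) ≈ A·exp(−λt)·cos(2π(t−φ)/τ) + c`, by multi-start variable
  projection: a period grid (16–40 h) is scored by profiled linear least
  squares, the best starts are refined over (τ, λ) with bounds, and ties
  go to the period nearest 24 h.
* **Fit error** = 1 − Pearson r between fit and detrended data (0 =
  perfect, 1 = uninformative, 2 = antiphase). Fits with error ≥ 0.5
  (cultured tissue) or ≥ 0.7 (whole animals) are excluded from group
  statistics.
* **Q10 temperature compensation**,
  `Q10 = (τ_cold / τ_warm)^(10 / (T_warm − T_cold))`:
  1 means the period is temperature-compensated, < 1 means the clock
  slows as it warms (over-compensation), the signature phenotype of
  peripheral fly clocks.
* **Shared-control estimation statistics**: each warmer group's periods
  are compared with the coldest group by an unpaired mean difference with
  a bootstrap (BCa or percentile) confidence interval, instead of
  p values.

## Worked example

A closed-loop run: simulate a two-temperature cohort whose true Q10 is
0.85 (reference period 21 h at 18 °C, 30 samples per temperature,
Gaussian counting noise), then push it through the full pipeline.

```r
library(circaluc)
cfg <- list(seed = 1,
            simulate = list(temperatures = c(18, 29), n_per_temperature = 30,
                            tau_ref_h = 21, t_ref_c = 18, q10_true = 0.85,
                            tau_sd_h = 0.5,
                            params = list(noise_model = "gaussian",
                                          noise_sd_cps = 10)),
            effects = list(n_boot = 1000))
res <- runPipeline(cfg)

res$summary[, c("temperature_c", "n", "tau_mean_h", "tau_sem_h")]
#>  temperature_c  n tau_mean_h  tau_sem_h
#>             18 30   21.10375 0.09703458
#>             29 30   25.07647 0.07691041

res$q10
#>  genotype  tissue t_cold_c tau_cold_h t_warm_c tau_warm_h delta_tau_h       q10
#>   sim-luc haltere       18   21.10375       29   25.07647    3.972719 0.8548756

effectsTable(res$effects[[1]])
#>  control test mean_difference   ci_low  ci_high n_control n_test n_boot ci_level method crosses_zero
#>       18   29        3.972719 3.721709 4.201688        30     30   1000     0.95    bca        FALSE
```

Reading this: the fitted group-mean period lengthens by ~4.0 h from 18 to
29 °C, giving Q10 ≈ 0.855 — the pipeline recovers the generating value
0.85 — and the shared-control interval (3.7–4.2 h, excluding zero) says
the lengthening is far beyond resampling noise.

The same arithmetic applied to published group means works directly:

```r
q10(computeQ10(21.0, 18, 25.2, 29))   # 0.8473... -> prints as 0.85
deltaTau(21.0, 25.2)                  # 4.2 h
```

`runPipeline()` also accepts a YAML config (`readRunConfig()`) and writes
`fits.csv`, `report.csv`, `effects.csv` and `pipeline.log` when
`output_dir` is set; `inst/scripts/circaluc-cli.R` wraps it for shell use
(`simulate`, `fit`, `summarize`, `compare`, `run`).

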