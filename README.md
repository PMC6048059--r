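# crowdihc

Aggregation, calibration and survival association for **crowdsourced
immunohistochemistry (IHC) scoring** of tissue-microarray (TMA) cores.

## The problem

Scoring IHC-stained TMA cores is traditionally an expert task: for each
core a pathologist estimates the proportion of cancer cells stained by
a marker (0–100%) and the staining intensity (0–3), combined into the
**H-score**

```
H = proportion (0–100) × intensity (0–3)    ∈ [0, 300]
```

Crowdsourcing replaces the expert with many untrained raters, each
classifying one tile of a core (a 6×6 grid; in practice only the
central 4×4 tiles contain enough tissue). Raters answer conditional
categorical questions — cancer present? which proportion bin? which
intensity? — under one of three bin schemes. This produces millions of
noisy categorical labels that must be turned into per-core and
per-patient H-scores that can stand in for expert scores in survival
analyses.

`crowdihc` provides the full chain, for analysts working with
crowd-scored IHC (or anyone who wants a tested reference for this kind
of bounded-score consensus problem):

* **Aggregation** — pooled means of bin midpoints / intensities per
  core, "no cancer" responses excluded; patient scores as means of
  corrected core scores.
* **Bias correction** — averaging bounded noisy scores overestimates
  near 0 and underestimates near 100, so aggregated scores are mapped
  to the expert scale by OLS with clipping; expert-scored cores are
  corrected by leakage-free 10-fold cross-validated prediction.
* **Agreement** — Spearman rank correlation (H-score, proportion) and
  quadratic-weighted kappa (intensity) with 1000-sample percentile
  bootstrap CIs.
* **Rater economics** — accuracy as a function of ratings per core,
  the analysis that justifies dropping from 25 to 5 raters per
  segment (80 ratings per core).
* **Survival** — Kaplan–Meier curves, log-rank tests and Cox
  proportional-hazards models (Efron ties) for patient H-scores, with
  combined-cohort quartile and median splits.
* **Synthetic crowds** — a seeded generator of ground-truthed cores,
  raters, expert scores and survival outcomes, so every stage is
  testable by parameter recovery.

See `vignettes/crowd-ihc-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Run the whole pipeline on a synthetic crowd (150 patients, two cores
each, 5 raters on each of the 16 central segments = 80 ratings/core,
12% expert-scored cores, survival generated with a protective hazard
ratio of 0.991 per H-score unit):

```r
library(crowdihc)
run_pipeline(list(n_patients = 150, seed = 1), "demo")
#> [synth] in=300 out=24000 (0.06s)
#> [aggregate] in=24000 out=300 (0.02s)
#> [correct] in=300 out=300 (0.01s)
#> [agree] in=36 out=3 (0.25s)
#> [survival] in=150 out=6 (0.99s)

read.csv("demo/agreement.csv")
#>   marker_id              metric estimate ci_low ci_high n_pairs n_bootstrap
#> 1        M1          spearman_h    0.979  0.939   0.991      36        1000
#> 2        M1 spearman_proportion    0.967  0.899   0.991      36        1000
#> 3        M1  qw_kappa_intensity    0.843  0.718   0.917      36        1000
```

Crowd and expert scores agree strongly (H-score Spearman 0.98 with a
bootstrap 95% CI of 0.94–0.99); intensity, the hardest question, still
reaches a weighted kappa of 0.84. The fitted corrections show the
expected boundary bias (slope > 1 with a negative intercept — crowd
scores are compressed toward the middle of the scale):

```r
read.csv("demo/corrections.csv")
#>   marker_id     target intercept slope n_fit
#> 1        M1 proportion    -6.561  1.14    36
#> 2        M1  intensity    -0.917  1.39    36
```

The Cox stage recovers the generative hazard ratio in each cohort
(truth: HR 0.991 per H-score unit):

```r
subset(read.csv("demo/cox_results.csv"), model == "univariable")
#>         cohort marker       model    term     coef    hr ci_low ci_high        p  n n_events
#> 1   cystectomy     M1 univariable h_score -0.01237 0.988  0.981   0.994 0.000153 68       32
#> 3 rt_1995_1999     M1 univariable h_score -0.00994 0.990  0.985   0.995 0.000254 45       31
#> 5 rt_2002_2005     M1 univariable h_score -0.01158 0.988  0.981   0.996 0.002103 37       23
```

Every CI covers 0.991; higher marker expression associates with lower
disease-specific mortality, as simulated.

The same pipeline is scriptable: `inst/cli/crowdscore` exposes
`synth | aggregate | correct | agree | curves | survival | run`
subcommands with `--config`, `--seed` and `--out` flags, driven by a
flat `key = value` config file.

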