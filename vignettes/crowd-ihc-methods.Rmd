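---
title: "Crowdsourced IHC scoring: models, calibration and what the tests establish"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowdsourced IHC scoring: models, calibration and what the tests establish}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdihc)
```

## The problem

Immunohistochemistry (IHC) on tissue microarrays (TMAs) is scored by the
H-score: the percentage of cancer cells stained by a marker (0–100)
multiplied by the average staining intensity (0–3), so 0 means no
positive cells and 300 means every cell positive at maximal intensity.
Expert scoring of hundreds of cores per marker is slow; crowdsourcing
replaces the expert with many untrained raters, each judging one small
tile of a core. `crowdihc` implements the complete analysis chain for
such data:

1. tile a core into a 6×6 grid and keep the central 4×4 block, where
   the tissue actually is;
2. aggregate noisy categorical responses into per-core proportion and
   intensity scores;
3. calibrate the aggregates against a small expert-scored subset by a
   clipped linear correction, with cross-validated prediction for the
   expert cores themselves so no score is corrected using its own
   error;
4. quantify crowd–expert agreement (Spearman rank correlation for
   proportion and H-score, quadratic-weighted kappa for intensity) with
   percentile bootstrap intervals;
5. measure accuracy as a function of the number of ratings per core;
6. relate patient-level H-scores to disease-specific survival with
   Kaplan–Meier curves, the log-rank test and Cox proportional-hazards
   models.

Because no raw crowd dataset of this kind is publicly deposited, the
package ships a first-class synthetic-crowd generator with known ground
truth; every downstream stage is validated by parameter recovery
against that truth.

## The response and aggregation model

A rater sees one segment and is asked up to three conditional
questions: is cancer present; if yes, which proportion bin; if the bin
is above zero, which intensity (1–3). Three categorical bin schemes are
supported (see `bin_scheme()`); bins are treated as half-open intervals
`(lower, upper]` with bin 0 reserved for exactly 0%, so the six bins
partition [0, 100] and a continuous truth can be censored into a bin
deterministically. A bin is mapped to a number by the arithmetic
midpoint of its printed label (0 for the zero bin) — unbiased under
within-bin uniformity; nothing in the downstream chain depends on the
mapping beyond monotonicity.

Aggregation (`aggregate_core()`) pools **all** responses of a core
across segments jointly rather than averaging per segment first: the
per-core proportion is the mean of bin midpoints over responses that
indicated cancer (bin-0 responses count as 0), and intensity is the
mean over responses with a positive bin. "No cancer" responses are
excluded from both means: either the tile really had no cancer (and the
response carries no staining information) or the rater was wrong (and
should not contribute). Cores whose responses are all "no cancer" are
retained with proportion 0 and an `all_no_cancer` flag rather than
dropped, so downstream stages can decide. Patients with several cores
get the unweighted mean of corrected proportion and intensity, and the
patient H-score is recomputed from those means so that it respects its
own bounds.

## Why a linear correction, and how leakage is avoided

Averaging noisy *bounded* scores is biased at the bounds: a core with
true proportion 0 can only be overestimated. The remedy is a linear
map from the crowd scale to the expert scale, fitted by ordinary least
squares of expert on crowd over the expert-scored subset, applied with
clipping into the target range (a corrected proportion of −5 becomes
0). Proportion and intensity are corrected by separate independent
models; the H-score is the product of the corrected components.

Expert-scored cores cannot be corrected by a model fitted on
themselves — that would make exactly the cores used for evaluation
look artificially good. `cv_correct_expert_cores()` therefore predicts
each expert core from a 10-fold cross-validated fit: a seeded random
permutation is cut into contiguous, maximally equal folds, and each
core's correction comes from the model fitted on the other folds. The
test suite verifies by direct refit that no prediction depends on the
held-out core's own expert value.

Correction happens at core level, before patient aggregation: the
calibration pairs are cores, and correcting first keeps the patient
mean a mean of calibrated quantities.

## Agreement statistics

Spearman's correlation is computed as Pearson correlation of mid-ranks
(average ranks for ties). The quadratic-weighted kappa uses weights
$w_{ij} = (i-j)^2/(k-1)^2$ and a Cohen-style expected matrix (outer
product of the observed marginals), appropriate for the two-fixed-rater
design of crowd consensus versus expert. Crowd intensity is a mean and
therefore continuous; it is discretised for kappa by rounding half-up
to {0, 1, 2, 3} (`discretize_intensity()`), an explicit and
configurable choice since the original analysis does not state one.
Confidence intervals are percentile bootstrap: 1000 resamples of the
core pairs, 2.5/97.5 percentiles, estimate on the full data.

## The synthetic world

The generator states one concrete world and the tests live in it:

* **Truth prior.** Patient-level true proportion is a mixture:
  25% exactly 0, 50% Uniform(0, 100), 25% exactly 100. The point
  masses sit *at* the bounds because that is where clipping and
  boundary bias act; the mixture mean (50) and variance have closed
  forms used by the recovery tests. True intensity is Uniform(1, 3)
  when any cells stain, 0 otherwise. Cores within a patient jitter by
  a 5% SD around the patient truth (bound patients stay at the bound).
* **Segments.** Central-16 cancer fractions are Beta(5, 2) (mean
  ≈ 0.71), outer-20 are Beta(1, 4) (mean 0.2) — outer tiles are
  mostly sparse, which is the empirical reason the central-16
  restriction is harmless.
* **Raters.** A segment with cancer fraction $f$ is called cancerous
  with probability $p_{\mathrm{fa}} + (1 - p_{\mathrm{fa}} -
  p_{\mathrm{miss}})f$ (defaults: false-alarm 0.05, miss 0.10).
  Reported proportion is truth plus Gaussian noise (SD 15%), clamped
  and censored into the scheme's bin; intensity is truth plus noise
  (SD 0.5), clamped to [1, 3] and rounded. These defaults are a
  plausible stand-in for untrained raters; with 80 ratings per core
  they produce crowd–expert agreement in the published 0.65–0.92
  range without being tuned to any specific value.
* **Experts.** A random 12% of cores (round half-up) get low-noise
  continuous observations of truth (SD 2% / 0.1).
* **Survival.** Event times are exponential with rate
  $\lambda_0 e^{\beta h}$, $\beta = \log 0.991$ per H-score unit by
  default (a protective marker of realistic magnitude),
  $\lambda_0 = 0.02$/month, independent exponential censoring at
  0.005/month; times are rounded to 0.1 month so ties occur, which
  exercises the Efron correction. Clinical covariates are drawn from
  realistic marginals but independent of survival — they are null
  adjustment variables, not confounders.

What the generator does **not** emulate: pixel-level images, rater
identity and learning, engagement dynamics, inter-marker correlation
within a patient, informative censoring, and real expert error
structure. A green test therefore establishes that the pipeline
recovers parameters *in this world*; it does not certify accuracy on
any particular real crowd.

## Numerical choices

* One global integer seed; every generator and resampling step draws
  from a sub-stream derived by hashing (seed, stage label), so adding
  a stage never shifts another stage's draws, and all seeds stay below
  $2^{31}$.
* Corrected scores are reported at a fixed $10^{-9}$ precision.
  Cross-validation folds fitted on exactly collinear data produce
  coefficients differing at the $10^{-14}$ level; without rounding,
  such fuzz breaks exact ties and destabilises rank statistics. One
  nanopercent is far below any measurement scale here.
* OLS uses the QR path of `lm.fit`; equality tests against the
  normal-equations solution use 1e−10 tolerances.
* Quartile cuts use type-7 quantiles with ties going to the lower
  quartile; median splits are strict (`> median` is high, ties low).
* Round-half-up (`floor(x + 0.5)`) is used wherever a half-way case
  must be deterministic (expert subset size, intensity discretisation),
  avoiding R's banker's rounding.
* Cox fits use Newton iteration with Efron ties as provided by the
  `survival` package; non-convergence is surfaced via a `converged`
  attribute rather than silently.

## Design decisions that were genuinely open

* **Expert score granularity.** Whether experts scored in the same
  bins as the crowd or continuously is unstated; the data types accept
  continuous values and the generator emits them. This matters for
  limiting behaviour: with *noiseless* raters, agreement with
  bin-censored expert scores is exactly 1, while agreement with
  continuous expert scores is capped (≈ 0.95 Spearman) by the bin
  censoring itself — ties, not noise. The test suite asserts both
  limits separately.
* **Bin-0 responses** enter the proportion mean as 0 (they assert "no
  staining", which is information) but contribute nothing to the
  intensity mean (no intensity question was asked).
* **Rater-curve bootstrap** redraws the per-core subsample and
  resamples the core pairing jointly, since the published error bars
  do not separate the two sources.
* **Subsampling unit** for the rater curves is the core ("ratings per
  image" is ambiguous); per-segment subsampling would be a small
  variation on the same machinery.
* **Median splits** default to the combined dataset, consistent with
  the quartile rule, with the per-cohort alternative available by
  subsetting before the call.

## Limitations

The correction is linear by construction; saturating bias near the
bounds would call for isotonic or spline calibration, deliberately out
of scope. No per-rater ability model is possible because responses are
anonymous. The sensitivity analysis using all raw observations with
per-patient clustering is not implemented (the clustering method is
unspecified in the source analysis). Proportional-hazards diagnostics
(scaled Schoenfeld residuals) are out of scope; the Cox fits here are
associations, not validated prognostic models.
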