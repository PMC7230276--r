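---
title: "Methods: HRCT fibrosis scoring and pneumonitis risk analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HRCT fibrosis scoring and pneumonitis risk analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfscore)
```

## The scoring model

The HRCT fibrosis score (HFS) is a semi-quantitative grade of pulmonary
fibrosis read from six lung regions: left and right lung at three axial
levels (the carina, the right inferior pulmonary vein, and midway between).
A reader partitions each region's parenchyma among four finding categories —
normal attenuation, reticular abnormality, reticular abnormality with
traction bronchiectasis, honeycombing — in 5% extent increments, the
extents summing to exactly 100. The region's points are the weighted extent
sum with weights 1–4 in category order, so a region lies in [100, 400] and
is linear in the extents: moving 5% of lung from one category to the next
heavier one adds exactly 5 points. The reader's HFS is the arithmetic mean
of the six region points, and the patient's HFS the mean across readers
(any subset of one or more readers is accepted). Averaging happens on the
final reader-level score, not on pooled region reads, which matches how two
independent reads are reconciled in practice and keeps each reader's score
a valid standalone measurement.

Emphysema is graded in the same six regions by the Goddard score: each
region's low-attenuation-area (LAA) extent is banded to 0–4 and the six
band scores are summed (0–24). The printed band thresholds leave gaps
(5–6%, 25–26%, 50–51%, around 75%); we close them with contiguous half-open
bands — ≤5 → 0, (5, 25] → 1, (25, 50] → 2, (50, 75] → 3, >75 → 4 — which
preserves every printed interior value and makes the banding total and
monotone.

Severity categories are likewise half-open: HFS exactly 100 is "no ILD",
(100, 200] mild, (200, 300] moderate, (300, 400] severe, and GS 0 none,
(0, 7] mild, (7, 15] moderate, (15, 24] severe. The published integer band
labels (101–200 and so on) cannot hold verbatim because reader-averaged
scores are non-integer (a patient averaging 122.5 is unambiguously mild),
so the half-open convention is the only order-preserving completion.
Severity and the analysis strata are assigned on the reader-averaged score;
assigning them per reader and then reconciling would need an arbitration
rule the measurement procedure does not define.

Two boundary conventions worth noting. First, extents must be on the 5%
grid; off-grid input is rejected by default rather than silently rounded,
because an off-grid value usually signals a unit or transcription error.
An explicit `allow_offgrid = TRUE` snaps to the nearest 5% with ties
rounded away from the normal category (a tie means genuine uncertainty, and
under-calling fibrosis is the costlier error here), the normal extent
absorbing the residual so the partition still sums to 100. Second,
reader-level HFS values live on a lattice of multiples of 5/6 points above
100 (one 5% step in one of six regions); not every printed score is
reachable by strict grid arithmetic, which is why patient-level averaging
also accepts per-reader score tables directly.

## Inter-observer agreement

Agreement between readers is quantified by the single-measure intraclass
correlation from the two-way subjects × raters ANOVA without replication.
The default is ICC(2,1) — two-way random effects, absolute agreement:

$$\mathrm{ICC}(2,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}$$

with $MS_R$, $MS_C$, $MS_E$ the subject, rater and residual mean squares.
We treat the two pulmonologists as interchangeable raters drawn from a
population of qualified readers, which is what absolute agreement models;
ICC(3,1) (consistency, raters fixed) is available via
`model = "consistency"` for the reader-pair-specific question. Confidence
intervals use the McGraw–Wong F-based construction with Satterthwaite
degrees of freedom; they are computed but only reported when asked for,
since the agreement analysis is descriptive. A matrix with no
between-subject variance yields a defined non-positive estimate with a
warning rather than an error.

## Prevalence and the 2×2 comparison

Prevalences are reported in percent with Wald (normal-approximation)
intervals $\hat p \pm z_{0.975}\sqrt{\hat p(1-\hat p)/n}$, which can extend
past 0 or 100 for rare outcomes; the Wilson score interval is available
behind `method = "wilson"` when a range-respecting interval is wanted. The
incidence comparison by ILD status is the Pearson chi-square test on the
2×2 table, without continuity correction by default (Yates via
`correct = TRUE`); with the event counts involved both variants give the
same qualitative answer.

## Time-to-event machinery

Follow-up time is measured in days from the first anti-cancer drug
administration; the event is the first drug-induced pneumonia only, with
death, hospital transfer, loss to follow-up and immune-checkpoint-inhibitor
initiation treated as non-informative right censoring (no competing-risks
model — the estimand is the cause-specific hazard, matching the censoring
definition). The 60-day post-treatment attribution window is a property of
the event label supplied in the data, not recomputed here.

`km_fit()` is the product-limit estimator over distinct times.
`logrank_trend()` tests an ordered trend across strata scored
$s_1 < \dots < s_K$: with $O_g$ and $E_g$ the observed and expected events
per group, $U = \sum_g s_g (O_g - E_g)$ and the variance sums the
hypergeometric term per distinct event time (times with a single subject at
risk contribute nothing); $U^2/\mathrm{Var}(U)$ is referred to
$\chi^2_1$, two-sided. The statistic is invariant under affine rescaling of
the scores, so the default equally spaced 0, 1, 2 for the strata
HFS = 100, (100, 110], > 110 is as general as any equal spacing; with two
groups it reduces exactly to the standard log-rank test.

`cox_fit()` maximises the Cox partial likelihood by Newton–Raphson with
step halving, Breslow tie handling by default (matching the behaviour of
the commercial software this analysis style is usually run in) and Efron
behind `ties = "efron"`. Numerics: covariates are centred internally for
conditioning (estimates are shift-invariant), convergence is declared at
max |score| < 1e-9 or max |step| < 1e-10 within 50 iterations, standard
errors come from the inverse observed information, and Wald intervals are
exponentiated to the hazard-ratio scale. A monotone partial likelihood
(complete separation in the risk sets) is detected by a coefficient passing
±15 on the log scale; the fit stops there, capped, flagged
`converged = FALSE` with a warning. A singular information matrix
(collinear covariates) is an error. The score test at the starting value is
returned because, at zero for a binary covariate on untied data, it equals
the two-group log-rank statistic — a useful internal consistency check.

The risk-factor table (`cox_table()`) fits one simple Cox model per
candidate factor with the reference levels: age < 70, female, ECOG-PS 0–1,
adenocarcinoma, clinical stage III, never-smoker, no gene abnormality, no
prior operation, no prior thoracic radiation; HFS and GS enter per point,
HFS centred at 100 (the per-point hazard ratio is unchanged by centring). A
factor level with zero events has a monotone likelihood and no finite
estimate; it is reported as `n/c` (not calculable) and excluded from that
variable's fit rather than dropped silently. The "replaced multiple"
analysis (`replaced_multiple()`) refits HFS in a bivariable model with one
adjuster at a time and reports the HFS coefficient from each — a
robustness check, not a multivariable model, which the small event count
would not support.

## What the synthetic cohort emulates

`cohort_spec()` encodes the study conditions the analysis assumes, and its
defaults are fixed rather than tuning knobs:

- n = 214 patients; ILD prevalence 0.285; all ILD mild: the HFS excess
  (HFS − 100) given ILD is exponential with mean 15 points, truncated to
  (0, 100] and discretised to the 5/6-point lattice reachable by six-region
  5%-grid arithmetic. The mean of 15 points puts meaningful mass in both
  the (100, 110] and > 110 strata, the shape a mild-ILD cohort would show.
- Event hazard log-linear in the excess:
  $\lambda \exp(\beta_{\mathrm{HFS}}(HFS - 100))$ with a true per-point
  hazard ratio of 1.16.
- The baseline hazard $\lambda$ is not free: it is solved deterministically
  (one-dimensional root of the closed-form event probability mixed over the
  discretised excess distribution) so the marginal event fraction equals
  19/214 ≈ 8.9%.
- Censoring: exponential dropout with mean 365 days (deaths, transfers,
  losses and ICI starts in a 7:1:1:1 split) plus an administrative horizon
  of 1460 days — a four-year study window; the follow-up distribution of
  the original cohort is unreported, so these are this package's choices,
  sized to an advanced-lung-cancer population where dropout, mostly death,
  dominates administrative censoring.
- Covariate marginals: male 0.67, ever-smoker 0.69, ECOG-PS 2–4 5/214,
  histology 0.64/0.16/0.14/0.06
  (adenocarcinoma/squamous/small-cell/other), stage 4/14/53/143 of 214
  (I/II/III/IV-or-recurrence), gene abnormality 63/214, Goddard category
  93/77/36/8 of 214, age normal(66, 10) clipped to 25–85. Prior-operation
  (0.25) and prior-radiation (0.30) marginals are not published for the
  reference cohort; these values are plausible for a mixed-stage
  chemotherapy population and are fixed once. Covariates are drawn
  independently — the joint distribution is unpublished — so the generator
  cannot exhibit real confounding (e.g. smoking × emphysema); the
  replaced-multiple "stability under adjustment" behaviour on synthetic
  data is therefore the no-confounding limit, not evidence about real
  cohorts.

Reader noise (`reader_noise_spec()`, `simulate_reads()`): each reader's
six-region total deviates from the patient's target HFS by a symmetric
lattice perturbation with an independent equiprobable sign. The magnitude
is m or m + 1 lattice steps with a mixing probability chosen so the noise
variance hits its calibrated value exactly despite the discrete grid, and
it is capped at the patient's own HFS excess, so a read can never cross the
100-point floor — patients without ILD are read as fully normal by every
reader, and no truncation or clipping ever occurs. Because of that, the
population intraclass correlation has the exact closed form
$\sigma^2_{\mathrm{subject}} / (\sigma^2_{\mathrm{subject}} +
\sigma^2_{\mathrm{noise}})$, and `icc_target = 0.96` calibrates
$\sigma^2_{\mathrm{noise}}$ against the cohort's target variance. Two
consequences to be aware of: the noise needed for a population ICC of 0.96
has a standard deviation of roughly 4 points, so a single reader average
deviates from the target by more than one lattice step (exact recovery
holds on the noise-free path, `noise_sd = 0`); and the zero-noise-at-100
feature means the model has heteroscedastic errors — the closed form holds
for the ANOVA expectations, which is what the ICC estimator consumes. The
optional category-confusion probability (reticular ↔ reticular with
traction bronchiectasis) adds variance outside this calibration and
defaults to 0. Goddard reads are split evenly across regions and are
noise-free by default.

Sampled follow-up times are rounded up to whole days, giving occasional
ties — deliberately, so tie handling is exercised on realistic input.
Everything is reproducible bit-for-bit from `(spec, seed)`.

## Test design and problem sizes

The suite checks every estimator against an independent route: the Cox
maximiser against a two-stage grid search of an explicitly coded partial
likelihood and against the reference `survival` implementation on random
tied and untied fixtures; the trend log-rank against `survival::survdiff`
in its two-group reduction; the ICC against `stats::aov` mean squares; the
Kaplan–Meier curve against the empirical survival function under no
censoring and a hand-computed censored fixture. Recovery simulations use
500 cohorts of n = 214 for the per-point hazard ratio and 200 replicates
for the ICC, sizes at which Monte-Carlo error is small enough to detect
meaningful bias while the whole suite stays fast; both compare the mean
estimate to the generating truth within three Monte-Carlo standard errors.

## Limitations

- The scoring engine consumes reader-supplied extents; it does not
  segment images, and exclusions (extensive pure ground-glass opacity,
  organised post-treatment lesions) must be folded into the partition
  upstream.
- Readers are assumed to use identical region definitions; region-placement
  disagreement is not modelled.
- The generator reproduces marginals and the hazard structure, not joint
  covariate dependence, reader bias (its rater effect defaults to zero), or
  moderate/severe ILD (the reference population had none), so passing tests
  demonstrate correctness of the machinery under the stated model, not
  validity of the score in new clinical populations.
- No proportional-hazards diagnostics, penalised or time-varying effects;
  the package fits what the analysis design calls for.
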