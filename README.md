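# hfscore

Quantitative HRCT fibrosis scoring and drug-induced pneumonitis risk
analysis for lung cancer cohorts.

## The problem

Pre-existing interstitial lung disease (ILD) is a major risk factor for
anti-cancer drug-induced pneumonia, but guideline-based ILD classification
misses mild fibrosis without honeycombing or traction bronchiectasis. A
semi-quantitative HRCT fibrosis score (HFS) grades exactly that: two readers
partition six lung regions (left/right lung at the carina, at the right
inferior pulmonary vein, and midway between) among four CT finding
categories on a 5% extent grid — normal attenuation (weight 1), reticular
abnormality (2), reticular abnormality with traction bronchiectasis (3),
honeycombing (4). Each region scores

    points = Σ_categories weight × extent%      ∈ [100, 400]

a reader's HFS is the mean of the six region points, and the patient's HFS
is the mean across readers. HFS = 100 is normal lung; (100, 200] mild,
(200, 300] moderate, (300, 400] severe ILD. Emphysema is graded in the same
six regions with the Goddard score (GS): low-attenuation-area extent banded
0–4 per region (≤5%, (5,25], (25,50], (50,75], >75%) and summed to 0–24.

This package implements the scoring engine and the full downstream risk
analysis: inter-observer agreement (ICC(2,1) from two-way ANOVA mean
squares), prevalence with Wald/Wilson confidence intervals, the chi-square
comparison of pneumonia incidence by ILD status, Kaplan–Meier cumulative
incidence, the trend log-rank test across ordered HFS strata
(HFS = 100, 100 < HFS ≤ 110, HFS > 110), and Cox proportional-hazards
models — simple and bivariable "replaced multiple" — fitted by
Newton–Raphson maximisation of the partial likelihood with Breslow or Efron
tie handling. A synthetic-cohort generator with the matching statistical
structure (covariate marginals, point-mass-plus-mild-band HFS distribution,
log-linear event hazard, right censoring, calibrated two-reader scoring
noise) makes every stage testable end to end without clinical data.

## Worked example

Score two patients read by one reader (`example_reads()` holds the region
partitions: patient A has 5–10% reticulation in five regions; patient B has
20–30% reticulation and emphysema with all six fields in the 51–75% LAA
band):

```r
library(hfscore)
patient_scores(example_reads())
#>   patient_id hfs gs ild_severity emphysema_severity hfs_stratum
#> 1          A 105  0         mild               none gt100_le110
#> 2          B 125 18         mild             severe       gt110
```

Patient A's 95/5 regions score (95×1)+(5×2) = 105 points each, so the HFS
is 105 — mild ILD in the (100, 110] stratum. Patient B's six Goddard region
scores of 3 sum to GS 18: severe emphysema.

Simulate a 214-patient cohort at the default spec (28.5% ILD prevalence,
true per-point hazard ratio 1.16, event fraction calibrated to 8.9%) and
fit the per-point HFS effect:

```r
spec <- cohort_spec()
cohort <- simulate_cohort(spec, seed = 7)
cox_fit(cohort$time_days, cohort$event, cohort$hfs - 100)
#> Cox proportional hazards fit (breslow ties): n = 214, events = 22
#>  term   hr        ci        p
#>    x1 1.15 1.11-1.19 7.77e-14
```

The estimated hazard ratio of 1.15 per HFS point (95% CI 1.11–1.19) says
each additional point of fibrosis score multiplies the pneumonia hazard by
~1.15 in this replicate; the generating truth is 1.16. Two-reader reads with
noise calibrated to a population ICC of 0.96 are recovered by the agreement
module:

```r
reads <- simulate_reads(cohort, seed = 8)
icc(ratings_matrix(reader_scores(reads), "hfs"))
#> ICC(2,1) absolute agreement: 0.958 (95% CI 0.945-0.968), n = 214 subjects, k = 2 raters
```

`analyze_cohort(cohort)` runs the whole pipeline (prevalence, chi-square,
per-stratum Kaplan–Meier, trend log-rank, the simple Cox table over all
candidate risk factors, and the replaced-multiple HFS models);
`write_results()` serialises it with a hashed manifest. A thin command-line
wrapper over the same functions lives at `inst/cli/hfscore.R`
(`score`, `agree`, `simulate`, `analyze` subcommands).

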