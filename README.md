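# asdsurv

Records-based surveillance of autism spectrum disorder (ASD) prevalence
among 8-year-old children, as an R package. It implements the multi-site,
multi-source active-surveillance computation used by the CDC ADDM Network
for the 2018 surveillance year — for epidemiologists, surveillance
methodologists, and anyone who needs the full pipeline (synthetic record
generation → case ascertainment → socioeconomic stratification →
estimation → report tables) runnable and testable end to end without
access to restricted child-level records.

## What it computes

**Case ascertainment.** Children aged 8 in the surveillance year (born
2010, resident for ≥1 day) are cases if their records, merged across
health, education, and service-program sources, document any of:

1. an ASD diagnostic statement by a qualified professional in an
   evaluation (directly documented, or historically reported with its
   age);
2. a special-education autism classification or eligibility;
3. an ASD ICD code — ICD-9 in [299.00, 299.99] or ICD-10 F84.\* except
   Rett syndrome (F84.2).

Inaccessible records contribute only transmitted ICD and
special-education codes; evaluations on them are invisible, reproducing
the code-driven under-ascertainment of sites with limited chart access.
Cases are partitioned into the seven Euler regions of the three
identification types.

**Estimation.** For a numerator *x* and denominator *n*, prevalence is
reported per 1,000 with the Wilson score interval

> center = (p̂ + z²/2n) / (1 + z²/n),  half-width = z·√(p̂(1−p̂)/n + z²/4n²) / (1 + z²/n),

with z = 1.959964. Prevalence ratios carry the Katz (log-normal) interval
exp(ln R ± z·√(1/x_a − 1/n_a + 1/x_b − 1/n_b)). Estimates with relative
standard error √(p̂(1−p̂)/n)/p̂ > 30% are suppressed (rendered "—"), and
ratios of suppressed estimates are suppressed. Proportions are compared
with Pearson chi-square, prevalence ratios across sites with the Woolf
homogeneity test, trends across census-tract median-household-income
tertiles with the Cochran-Armitage test, and median age differences with
a permutation test (exhaustive when `choose(n_x+n_y, n_x)` ≤ 20,000).
Rates and ratios are rounded half-away-from-zero to one decimal at the
reporting boundary only.

**Synthetic data.** A seeded generator emulates the study conditions —
11 site presets with the published population sizes, demographics, source
availability, record accessibility, and identification-type mixtures —
so every downstream statistic is exercised on data with the right
structure. See the methods vignette
(`vignettes/surveillance-methods.Rmd`) for the generative model and all
design choices.

## Worked example

Printed-count arithmetic — the published network totals reproduce
exactly:

```r
library(asdsurv)
est <- prevalence(5058, 220281)          # cases / population aged 8
render_estimate(est)
#> [1] "23.0 (22.3-23.6)"                 # per 1,000, Wilson 95% CI

m <- prevalence(4111, 220281 * 0.511)    # male cases / male denominator
f <- prevalence(945,  220281 * 0.489)
render_estimate(prevalence_ratio(m, f))
#> [1] "4.2 (3.9-4.5)"                    # male:female ratio, Katz 95% CI
```

A full synthetic network run:

```r
bundle <- run_pipeline(scenario_preset("network"), seed = 1)
bundle
#> <report_bundle> 220281 children, 4996 cases, 11 site(s)
#>   overall prevalence: 22.7 (22.1-23.3) per 1,000; M:F ratio 4.3 (4.0-4.6)

bundle$table2[, c("site", "n_with_asd", "overall", "mf_ratio")]
#>    site       n_with_asd overall          mf_ratio
#>  1 arizona           350 26.3 (23.7-29.1) 3.7 (2.9-4.8)
#>  2 arkansas          365 23.6 (21.4-26.2) 4.6 (3.5-6.0)
#>  3 california        547 36.3 (33.4-39.4) 5.3 (4.2-6.6)
#>  ...
#> 12 total            4996 22.7 (22.1-23.3) 4.3 (4.0-4.6)
```

Each site row is the site's ascertained case count, its prevalence per
1,000 with the Wilson interval, and the male:female prevalence ratio with
the Katz interval; one seeded realization scatters around the configured
site profiles (California highest, Missouri — the education-blind site —
lowest). `bundle$table4` gives the identification-type shares,
`bundle$fig1` prevalence by income tertile with the trend p value, and
`bundle$fig2` the Euler-region counts. `run_pipeline(..., outdir = "out")`
writes every table as CSV plus a JSON run manifest; the same pipeline is
scriptable from a shell via `inst/cli/asdsurv.R`
(`generate | ascertain | estimate | report | all`).

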