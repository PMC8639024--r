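---
title: "Records-based ASD surveillance: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Records-based ASD surveillance: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

asdsurv implements the computational core of multi-source, records-based
active surveillance of autism spectrum disorder (ASD) among 8-year-old
children, in the design used by the CDC ADDM Network for the 2018
surveillance year: children born in 2010 and resident in a site's catchment
for at least one day of 2018 are ascertained as ASD cases from provider
records, and prevalence is estimated against demographic population
denominators. This vignette explains the model behind each stage, the
parameters that matter, the numerical conventions, and the choices we made
where the design left room.

## The case definition and record semantics

A child meets the case definition when any of three indicators is
documented anywhere in their merged records:

1. a written ASD diagnostic statement by a qualified professional in a
   developmental evaluation — either documented directly or historically
   reported (an evaluation noting a previous diagnosis and its age);
2. a special-education autism classification (primary exceptionality of
   autism, or an evaluation concluding autism eligibility was met);
3. an ASD ICD billing code: ICD-9 in [299.00, 299.99], or ICD-10 in the
   F84 family *except* Rett syndrome (F84.2 and extensions). Short billing
   dialects are normalized ("299.0", undotted "F840"); unparseable text is
   logged and treated as a non-indicator, never an error.

Records are merged across sources by union, with one asymmetry that drives
the package's under-ascertainment behaviour: an *inaccessible* record (one
that could not be fully reviewed) contributes only its transmitted trigger
codes — ICD codes and special-education eligibilities — while evaluations
and cognitive tests on it are invisible. A diagnostic statement on an
inaccessible record therefore never sets the diagnosis indicator. This is
the mechanism by which sites with low record accessibility ascertain cases
mainly through codes.

Two points the design leaves open are resolved as follows and used
consistently everywhere:

* **Transmitted eligibility codes count.** A special-education autism
  eligibility satisfies clause 2 even when its record is inaccessible,
  mirroring the treatment of ICD codes. (Both are transmitted
  administratively; only evaluation *content* requires manual review.)
* **"Ruled out more recently" requires something to be more recent
  than.** The flag is true only when the maximum ruled-out age strictly
  exceeds the maximum age of a confirming diagnosis or eligibility; equal
  months cannot be ordered at month resolution, and a child whose only
  indicator is an ICD code (no confirming diagnosis or eligibility age)
  is never counted as ruled-out-more-recent.
* **Cognitive ties.** The cognitive band comes from the most recent
  (largest age) accessible entry; at equal ages a test score beats an
  examiner statement, and remaining ties break toward the higher score.
  Scores map as ≤70, 71–85, >85, with both boundaries inclusive on the
  left band.

## The synthetic-record generator

The generator exists so every downstream stage is testable without any
restricted data. Its defaults *are* the network-level study conditions of
the 2018 surveillance year; per-site presets carry the published site
profiles (population, % male, race/ethnicity mix, source availability,
record accessibility, identification marginals, cognitive-data
availability, median evaluation and diagnosis ages). Two modelling
conventions:

* **Ages are integer months, no calendar dates.** Every reported age
  statistic is in months; generating months directly avoids date
  arithmetic conventions. Evaluation and diagnosis ages are log-normal,
  truncated by clamping to [12, 107] months (a child aged 8 in the
  surveillance year has at most 107 observable months); log-normal gives
  the right-skew of diagnosis ages under an age-8 observation ceiling.
  Medians parameterize the log-scale mean (`meanlog = log(median)`), with
  `sdlog` 0.35 (diagnosis) and 0.40 (first evaluation) chosen to give
  realistic interquartile spreads of roughly ±30% around the median.
* **Identification types are sampled per case, independently across
  children**, from a seven-region mixture over the non-empty combinations
  of the three indicators. The network default mixture is calibrated to
  the published network shares — 75.8% any diagnostic statement, 18.8%
  special education without one, 5.4% ICD only, 73.5% with at least two
  types, and marginal shares 66.7% (ICD) and 61.7% (special education).
  These constraints pin down six of the seven regions; the free region
  (special education + ICD without a diagnostic statement) is set to
  0.10, in the middle of its feasible range [0, 0.188]. Site presets
  instead fit their three published *marginal* shares exactly, via the
  unique joint of three independent Bernoulli indicators conditioned on
  their union (a one-dimensional fixed point solved by `uniroot`);
  per-site Euler regions are not published, so independence-given-union
  is the minimal completion.

Other generator behaviour worth knowing:

* Sex-specific true prevalence is derived from the overall prevalence `p`,
  male share `m`, and male:female rate ratio `r` as
  `p_f = p / (1 - m + r m)`, `p_m = r p_f`.
* Preset `true_prevalence` is set to each site's *published ascertained*
  prevalence — surveillance has no access to a truer value — so a
  full-access run of a preset reproduces the printed rates in
  expectation.
* Record accessibility is drawn per record. About 20% of diagnoses enter
  the record only as a historically reported prior diagnosis inside a
  later evaluation (constant `P_REPORTED_PRIOR_DX`), exercising the
  reported-age path of the earliest-diagnosis statistic.
* Suspected and ruled-out conclusions are inserted with the configured
  probabilities; ruled-out ages are placed strictly before or strictly
  after the confirming age so the configured more-recent share is
  realized. Only cases carrying a diagnosis or eligibility indicator can
  draw a ruled-out conclusion (see the more-recent convention above).
* Sites without an education data source still *sample* special-education
  indicators but never emit education-source records, so special
  education is generated-but-unobservable there. This is deliberate: it
  makes ascertained prevalence strictly lower at an education-blind site
  than at an otherwise identical full-access site, the qualitative
  sensitivity the surveillance design reports.
* Non-case children carry, at the `false_trigger_rate` (default 5 per
  10,000), a record whose only code is F84.2 (Rett syndrome) — a
  requested code that is *not* an ASD indicator. These children must
  never be ascertained.
* Tract median household incomes are uniform over the configured range
  and tract child counts follow a symmetric multinomial. Real income
  distributions are neither uniform nor independent of demographics; the
  point is only to exercise the tertile machinery. 6.4% of children have
  no geocodable tract by default.
* Race/ethnicity, sex, socioeconomic tertile, and identification type are
  generated independently. The design reports no joint distribution, so
  none is invented; consequences are noted under Limitations.

## Denominators and socioeconomic tertiles

Demographic denominators are tabulated from the generated children, so the
conservation identity (cells sum to the site population) holds by
construction; race-specific denominators exclude children coded
other/multiracial. Census-tract denominators for 8-year-olds are estimated
as one fifth of the tract's count of children aged 5–9, fractions
preserved.

Tracts from *all sites combined* are ranked by median household income
(ties broken by tract id, which makes the assignment invariant to input
order) and cut into three approximately equal-population groups weighted
by the estimated 8-year-old population: a tract is `low` when its
cumulative population upper bound is at most one third of the total,
`high` when its lower bound is at least two thirds, and `medium`
otherwise. Whole tracts are never split. With realistic frames (each
tract's population small against a third of the total) each tertile lands
within one tract's population of exact thirds; with pathologically large
tracts the middle group absorbs both boundary-straddling tracts, and the
tests bound it accordingly. Tertile weighting by the estimated age-8
population (rather than another age band) is an assumption; it keeps the
SES denominators and the tertile cuts on the same scale.

SES-stratified prevalence uses the fractional tract-sum denominators, not
integer child counts, and children without a tract contribute to overall
but not SES-stratified numerators.

## Estimation conventions

* **Wilson score intervals** for all prevalence CIs: center
  `(p̂ + z²/2n) / (1 + z²/n)`, half-width
  `z √(p̂(1−p̂)/n + z²/4n²) / (1 + z²/n)`. At a zero numerator the lower
  bound is exactly zero. Validated against numeric inversion of the score
  test to 1e-9.
* **Katz (log-normal) intervals** for prevalence ratios:
  `exp(ln R ± z √(1/a − 1/n_a + 1/b − 1/n_b))`. The surveillance reports
  do not state their ratio-interval method; the Katz interval reproduces
  the published network male:female bounds (3.9–4.5), which is how the
  choice was validated.
* **Suppression** uses the binomial relative standard error
  `√(p̂(1−p̂)/n) / p̂ > 0.30`; the RSE definition is not stated in the
  design, and the binomial form implies the familiar rule of thumb that
  numerators below ~12 are suppressed. Ratios of suppressed estimates are
  suppressed. Suppressed cells render as an em dash.
* `z` is fixed at 1.959964 (the normal 97.5th percentile); the difference
  from 1.96 is far below reporting resolution but is pinned for
  reproducibility.
* **Rounding** is half-away-from-zero to one decimal, applied *only* at
  the reporting boundary. Internal arithmetic is unrounded — the printed
  male:female ratio 4.2 is reproducible only from unrounded sex-specific
  prevalences.
* **Pearson chi-square** (no continuity correction) compares proportions;
  **Woolf homogeneity** compares log prevalence ratios across strata with
  inverse-variance weights, excluding (and logging) strata with a zero
  numerator; the **Cochran-Armitage** z uses equally spaced scores 0, 1, 2
  over the SES tertiles and accepts fractional denominators. Degenerate
  trend inputs (no cases, or all cases) return p = 1.
* The **permutation median test** uses `|median(x) − median(y)|` with
  central-order-statistic averaging (so half-month medians like 40.5
  arise naturally). When the number of distinct label arrangements
  `choose(n_x + n_y, n_x)` is at most 20,000 it enumerates exhaustively
  and reports the exact tail proportion; otherwise it draws the
  configured number of Monte-Carlo permutations under a mandatory seed
  and uses the add-one estimator `(count + 1)/(B + 1)`, which can never
  return zero.

## What the validation shows — and does not show

The test suite checks, among others: exact reproduction of the published
network arithmetic from printed counts; Wilson-versus-score-inversion
agreement on a grid up to n = 500 and ~95% coverage over 2,000 simulated
binomial draws at p = 0.023, n = 20,000; exhaustive-versus-Monte-Carlo
agreement of the permutation test; type-I error near 5% for Woolf (11
homogeneous strata) and Cochran-Armitage (flat prevalence) over 1,000
replicates each; mixture-marginal recovery over 100 replicates; Wilson-CI
coverage of the configured truth by the full generate → ascertain →
estimate pipeline over 200 replicates at the network scale (n = 220,281,
prevalence 0.023, full record access); and strictly lower ascertainment at
an education-blind site over 100 paired replicates. These problem sizes
are the package's validation conditions and are fixed in the tests.

Passing these tests shows the pipeline is faithful to its own generative
model. It does *not* show fidelity to real surveillance data: real records
correlate identification type with race, SES, and site practices; real
income distributions and tract populations are far from uniform or
symmetric-multinomial; real evaluations carry free text that must be
clinically adjudicated (out of scope here — conclusions are stored as
labels); and real accessibility failures cluster by provider, not per
record. The generator is a study-conditions emulator, not a population
model.

## Known limitations

* No joint structure between demographics and identification processes
  unless configured; disparity analyses on synthetic data are therefore
  exercises of the machinery only.
* The suspected/ruled-out generator targets marginal shares; joint timing
  patterns (e.g., multiple rule-outs) are not modelled.
* ICD codes are drawn from a small representative pool; code-frequency
  realism is not attempted.
* The previous, symptom-based case definition is out of scope, as are
  birth-certificate linkage, real geocoding, and school-enrollment
  denominator adjustments.

```{r example}
library(asdsurv)
bundle <- run_pipeline(scenario_preset("network"), seed = 1)
bundle$table2
```
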