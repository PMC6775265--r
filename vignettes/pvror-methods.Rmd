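---
title: "Methods: disproportionality, adjusted RORs and time-to-onset in pvror"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality, adjusted RORs and time-to-onset in pvror}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Spontaneous reporting systems (SRS) such as FAERS collect individual case
safety reports (ICSRs): one suspected adverse-reaction report per patient,
carrying demographics, the drugs taken with their role codes, and the
reactions coded as MedDRA preferred terms (PTs). SRS data have no
denominator — we never observe how many patients took a drug without an
event — so risk cannot be estimated directly. What can be estimated is
*disproportionality*: whether a given reaction is reported relatively more
often with a given drug than with everything else in the database. `pvror`
implements an end-to-end disproportionality workflow for hemorrhagic
reactions under direct oral anticoagulants, together with a synthetic-data
generator that makes every stage testable against known truth.

# Data model and ingestion

A `report_set` holds three tidy tables keyed by `primary_id` (one row per
report *version*): demographics, drug exposures (with roles
suspect-primary/secondary, concomitant, interacting), and reactions. Dates
are stored as ISO-8601 prefixes (`"2014"`, `"2014-03"`, `"2014-03-21"`) so
the completeness level (`Y`/`YM`/`YMD`) travels with the value; only fully
complete dates are used for latency arithmetic. The FAERS-style reader
accepts `$`-delimited quarterly tables through a user-supplied column map,
never drops a row for an unparseable field (values become missing and are
counted in the provenance log), converts age-unit codes to years
(18 `MON` = 1.5 years) and sets ages above 120 years missing as a
plausibility guard.

**Deduplication.** The same case reaches the database repeatedly from
different reporting sources. Following the convention of keeping only the
most recent case version, `deduplicate()` keeps the greatest `primary_id`
per `case_id` — report identifiers increase over time in FAERS-style
systems, so the greatest id is a faithful proxy for the newest version.
Identical ids (which cannot arise through the constructor) would fall back
to first-encountered with a warning.

**Completeness filter.** The adjusted model requires reporting year, age and
sex; `filter_complete()` drops reports missing any required field and logs
per-field counts. Filtering on a union of fields equals sequential
filtering, a property the tests exercise.

# Event definition

An adverse event is defined as a set of preferred terms built by
intersecting a standardized MedDRA query (the clinical concept, e.g.
hemorrhage) with a system organ class (the anatomical site, e.g.
gastrointestinal disorders): only PTs on *both* lists qualify. MedDRA is
licensed, so term lists are user-supplied CSVs (`set_name`, `pt_code`); the
generator ships synthetic lists sized like realistic SMQ-by-SOC
intersections (152 gastrointestinal terms). Whether the supplied SMQ export
is narrow or broad scope is the user's choice; the package treats the list
as authoritative. A report is a *case* when any of its reactions is in the
effective set; reports without reactions are non-cases. Case status is per
report, not per drug–reaction pair.

# Crude and stratified reporting odds ratios

For each drug the analysed reports are cross-classified into the 2×2 table
(a = exposed cases, b = exposed non-cases, c = unexposed cases,
d = unexposed non-cases), where "exposed" means at least one exposure with a
suspect role (configurable). The reporting odds ratio is

$$\mathrm{ROR} = \frac{a/c}{b/d} = \frac{ad}{bc},\qquad
95\%\ \mathrm{CI} = \exp\!\Big(\ln \mathrm{ROR} \pm 1.96
\sqrt{\tfrac1a+\tfrac1b+\tfrac1c+\tfrac1d}\Big).$$

A drug–event pair is flagged as a **signal** when the CI lower limit exceeds
1 and at least two exposed cases exist. If any cell is zero, 0.5 is added to
all four cells (Haldane–Anscombe) and the result flagged `corrected`; a
table with a = 0 before correction can never signal. The 1.96 quantile is
hard-coded as the conventional 95% level but exposed as an argument.

Age-stratified RORs split reports at 60 years into `[0, 60)` and
`[60, ∞)` — the elderly reading of "60 and over" is used because it is the
one consistent with how stratified results are reported downstream; reports
with missing age are excluded from every stratum. The 65-year definition of
"elderly" used by the WHO is available by passing a different stratum
specification.

# The covariate-adjusted model

Crude disproportionality is confounded by reporting year, age and sex. The
adjusted analysis fits a multiple logistic regression of case status on:

* `year_c` — reporting year, entered **continuous and mean-centred**. A
  categorical year coding would multiply the term count thirteen-fold;
  the continuous coding is the parsimonious reading and the
  likelihood-ratio statistic is invariant to affine rescaling of the
  column (tested).
* `age60` — indicator of age ≥ 60, with the 0–59 group as reference.
* `female` — sex indicator.
* one 0/1 indicator per study drug (suspect-role exposure), and
* pairwise interactions of `age60` and `female` with each other and with
  each drug. Year-by-drug interactions are excluded by default.

Fitting is maximum likelihood via iteratively reweighted least squares
(`stats::glm.fit`) with a relative-deviance tolerance of 1e-12 and at most
100 iterations; the covariance is the inverse observed information. Any
coefficient exceeding 15 in absolute value flags (quasi-)separation and
marks the fit non-converged — adjusted RORs are never reported from such a
fit. With a single drug indicator and no other covariates the exponentiated
coefficient equals the crude ROR exactly, a cross-module identity the tests
verify to 1e-6.

**Stepwise selection.** Terms are screened forward and backward at a
likelihood-ratio significance level of 0.05 for both entry and removal (one
level is used for both directions). The statistic is the difference in
−2 log-likelihood, referred to χ² with one degree of freedom per term. A
forward step adds the eligible candidate with the smallest p-value when it
is ≤ 0.05; a backward step removes the included term with the largest
p-value when it exceeds 0.05; the search alternates until neither fires.
Weak heredity is enforced by default: an interaction becomes eligible only
while both parents are included, and a parent cannot leave while one of its
interactions stays (which is why a main effect with a large p-value can
legitimately remain in the final model). Every move is recorded in a
selection trace. Adjusted RORs are the exponentiated coefficients with Wald
95% CIs on the odds-ratio scale; per-term p-values are likelihood-ratio
tests of dropping that term alone.

# Time-to-onset analysis

Latency is counted from the patient's first prescription of the drug to the
occurrence of the event: per qualifying report (a case exposed to the drug),
the *earliest complete* start date among that drug's exposures and the
earliest complete onset date among event-matching reactions are used.
Reports with an incomplete date on either side are excluded and counted.
The day count is inclusive — `duration = onset − start + 1` — so a same-day
onset is 1 day; the Weibull likelihood needs strictly positive support and
the convention is switchable (`include_same_day = FALSE` excludes same-day
onsets instead). Onsets before the start are excluded as negative; the
analysis window is 365 days after the start and longer latencies are
excluded as beyond-window. The fit is a plain two-parameter Weibull MLE on
the within-window sample, mirroring the fixed-window procedure; no
truncation-likelihood correction is applied, which biases the shape upward
slightly when an appreciable mass lies beyond the window (for the shipped
study conditions that mass is below 3%).

The shape is obtained as the unique root of the profile score equation

$$\frac{n}{\beta} + \sum_i \ln t_i -
  n\,\frac{\sum_i t_i^{\beta}\ln t_i}{\sum_i t_i^{\beta}} = 0,$$

solved by Newton iteration (tolerance 1e-10, at most 200 iterations) on
durations rescaled by their geometric mean for numerical stability; the
scale follows in closed form as $\hat\alpha = (\tfrac1n\sum_i
t_i^{\hat\beta})^{1/\hat\beta}$. The profile score is strictly decreasing in
β, so the root is unique; the tests pin the solver against a dense 2-D
grid-search of the likelihood and against an independent survival-regression
fit. 95% CIs are Wald intervals on the log-parameter scale from the inverse
observed information (a numerically differentiated Hessian at the optimum);
a profile-likelihood CI was considered and not adopted since the Wald
interval's coverage is within [0.93, 0.97] at the sample sizes used here
(verified by simulation in the acceptance tests).

The **hazard class** is read off the shape CI: `increasing` when the lower
limit exceeds 1 (early risk grows with time on drug), `decreasing` when the
upper limit is below 1 (front-loaded risk), otherwise `constant`
(exponential, memoryless). Summaries report the empirical median and
quartiles (linear interpolation between order statistics, the default
sample-quantile definition), the fraction of onsets within 30 days, a
histogram over the window, and additionally the Weibull-fitted median
$\hat\alpha (\ln 2)^{1/\hat\beta}$ since it is not stated whether published
medians of this kind are empirical or fitted — the empirical one is the
primary output here.

# The synthetic-data generator

The generator emulates the *structure* the analysis relies on, with a
ground-truth ledger recorded before any corruption is applied:

* demographics: uniform reporting years, a two-component truncated-normal
  age mixture (modes near 45 and 72 years, the bimodal adult/elderly shape
  typical of anticoagulant reporting), configurable sex balance;
* exposures: independent Bernoulli per drug (or mutually exclusive), with
  suspect-role mixes — study drugs default to suspect roles only so the
  exposure that drives the event model is exactly the exposure the
  analysis counts;
* events: Bernoulli with a logistic linear predictor in year (centred at
  the middle of the year range), the age-60 indicator, sex, drug
  indicators and configurable pairwise interactions — the same model family
  the adjusted analysis fits, so recovery is a well-posed question;
* reactions: cases draw at least one PT from the event pool (the SMQ∩SOC
  intersection), everyone draws Poisson-many decoy PTs from pools sized
  like realistic term lists (152-term intersection, SMQ-only and SOC-only
  margins, plus unrelated decoys);
* latencies: the causal drug's start date is uniform within the reporting
  year and the onset is start + a Weibull draw **rounded up to whole
  days**, so the generator's support and the inclusive day-count convention
  agree on (0, 365];
* missingness: missing-completely-at-random per field, applied after the
  truth is recorded; date missingness degrades half the affected values to
  year-month completeness and removes the rest;
* duplicates: a configured fraction of reports get one extra version with
  a higher primary id and one perturbed non-analysis field (the source
  tag), so "most recent version wins" is exercised without corrupting the
  ledger's covariates.

Three presets define the study conditions used throughout the tests:
`"null"` (all log-odds zero), `"paper_like"` (four anticoagulants with
odds-ratio targets between about 7 and 20, female-by-drug ratio-of-odds
1.5, an age-by-sex interaction of 1.15, realistic missingness and 10%
duplicates), and `"tto_profiles"` (three drugs with Weibull shapes 0.7, 1.0
and 1.5 under exclusive exposure and complete dates).

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real SRS data: reporting dynamics (stimulated
reporting, media effects), informative missingness, drug-name noise beyond
exact synonyms, PT frequency skew, multi-drug causality and protopathic
bias, and duplicate versions that disagree on analysis fields. Results on
synthetic data validate the *machinery*, not the epidemiology.

# Numerical choices and degenerate inputs

* Haldane–Anscombe +0.5 on any zero cell, flagged; all-zero tables give an
  undefined, non-signalling result.
* IRLS: relative-deviance tolerance 1e-12, 100 iterations; separation guard
  |coef| > 15; singular designs are fatal with the aliased columns named.
* Zero-variance design columns (e.g. a drug nobody took) are dropped with a
  warning, along with interactions built on them.
* Weibull fits require at least 10 durations (configurable) and at least
  two distinct values; whole-day rounding inflates the fitted shape of
  sub-exponential (β < 1) profiles because short latencies pile up at one
  day — the hazard classification is unaffected in the shipped conditions,
  but shape point estimates for β < 1 should be read with this in mind.
* Quantiles use linear interpolation between order statistics throughout.
* Stepwise aborts with the full trace if the add/remove loop exceeds twice
  the candidate count.

# Problem sizes

The test suite runs the recovery checks at the sizes the properties need:
parameter recovery of the full interaction model at 200,000 reports,
stepwise type-I control over 200 replicates of 20,000 reports, Weibull
shape bias and CI coverage over 500 replicates of 1,000 durations, and
determinism of the full pipeline at 20,000 reports. The `analysis/` scripts
use 50,000 reports as a comfortable desk-scale default.

# Known limitations

* The ROR is a reporting association, not a risk estimate; no denominator
  exists in SRS data and the package makes no causal claims.
* Only the ROR family is implemented (no PRR, Bayesian shrinkage or EBGM).
* The fixed 365-day window is used without a truncation-corrected
  likelihood (by design, to mirror the fixed-window procedure); a corrected
  likelihood would be the natural extension.
* Drug-name normalisation is an exact-match synonym map after case-folding;
  fuzzy matching and dictionary-based batch conversion are out of scope.
* First prescription with several therapy start rows is resolved as the
  earliest complete date — an interpretation, since reduction rules for
  multiple starts are rarely published.
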