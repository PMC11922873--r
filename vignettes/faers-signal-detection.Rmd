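---
title: "Methods: disproportionality signal detection for FAERS reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality signal detection for FAERS reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the screening and
estimation model, the parameters that matter and why they default as they
do, the numerical choices, and what the synthetic validation does and does
not establish about real spontaneous-reporting data.

## The problem and the data model

Spontaneous adverse-event reporting systems such as FAERS collect case
reports — one report per patient episode, each listing one or more drugs
(with role, route and verbatim names), one or more reaction preferred
terms (PTs), indications, demographics and serious-outcome codes. Reports
are re-published across quarters as new *case versions*, so report-level
analysis must first deduplicate.

The package's unit of analysis is the deduplicated report. A `faers_cases`
object holds five linked tables (demographics, drugs, reactions,
indications, outcomes) keyed by `case_id`, the relational form the raw
FAERS tables already have. Deduplication keeps, per `caseid`, the highest
`caseversion` and breaks ties by the highest `primaryid` — FDA's
recommended practice. The rule matters: screening-stage counts are not
comparable across analyses that deduplicate differently, which is one
reason published flowchart counts are generally not reproducible exactly.

Field harmonization happens at deduplication time. Ages are converted to
years from their unit codes (`YR`, `DEC`, `MON`, `WK`, `DY`; a missing
unit with a value in (0, 120] is taken as years); the age bands are
`<20`, `20–50`, `50–65`, `≥65`, `unknown` — the juvenile- and
early-onset-Parkinson's cut points. Weights convert `LBS` to kg
(×0.453592) and values outside (20, 300) kg become unknown; entry noise in
FAERS weight fields is well known and a closed plausibility window is
preferable to propagating a 7,000 kg patient. Routes, drug roles,
reporter occupations and country groups map onto closed vocabularies
through editable TSV dictionaries; unknown codes degrade to
`unknown`/`other` with a warning rather than an error, because a single
exotic country code should never abort a 20-year extraction.

## The screening cascade

Four pure per-report predicates, applied in a fixed order with counts
recorded after each stage:

1. **Drug match.** A report enters a cohort when at least one drug entry
   matches the target substrings (brand and generic names, matched
   case-insensitively against both the verbatim name and the active
   ingredient string) *with a suspect role*, and at least one entry
   matches the levodopa partner patterns with a suspect role. Combination
   products (one row whose ingredient string names both levodopa and the
   DCI) satisfy both requirements by design. Suspect roles default to
   primary + secondary suspect; concomitant mentions do not qualify.
2. **Oral route**, tested on the matched target/partner entries only —
   an unrelated transdermal co-medication must not exclude a report.
   Unknown routes are excluded: an oral-only inclusion rule read
   conservatively. A report listing the product both orally and as an
   intestinal infusion is retained on the oral entry.
3. **Indication.** A Parkinson's-disease indication term must be attached
   to a matched drug entry (indication rows without a drug link count
   report-wide); reports listing Parkinson's disease itself as a
   *reaction* are excluded (indication bias), as are reports with any
   dementia/psychosis-family term among reactions or indications. The PD
   family defaults to {Parkinson's disease, idiopathic Parkinson's
   disease}; "parkinsonism" is deliberately absent — it names a symptom
   complex, not the disease.
4. **System-organ-class restriction** to nervous system disorders and
   general disorders/administration site conditions, the two SOCs housing
   motor-fluctuation and dyskinesia terms. Retained reports keep their
   full reaction list, but an *analysis view* masks non-whitelisted PTs;
   counting for endpoints and AE totals happens on that view.

Because each filter is a pure predicate, the terminal cohort is invariant
to stage order; only the trace changes. Reports matching both drug
queries are retained in both cohorts and flagged (`drop_dual = TRUE`
removes them); with report counts the paper-scale ratio of ~5:1 between
the two cohorts, dual matches are rare and retention is the less
distorting default.

## Composite endpoints

On-off phenomenon and freezing phenomenon exist as PTs and are matched
exactly (after canonicalizing case and whitespace). Dyskinesia and
wearing-off are composites and are matched as lower-case substrings:
{dyskinesia, dystonia, hyperkinesia, ballismus, alien limb syndrome} and
{therapeutic response shortened, therapeutic response incomplete}. The
substring mode deliberately reaches compound terms such as "tardive
dyskinesia"; no exclusion list ships by default, and the dictionary is an
editable TSV so a reviewer can tighten it. Matching applies to PTs only,
not verbatim reaction text. A report contributes at most once per
endpoint, and every hit records the matching PTs for audit. The loader
rejects dictionaries whose endpoint member sets overlap.

## Disproportionality statistics

All three statistics act on the report-level 2×2 table for one drug
cohort against a comparator: `a` cohort reports with the endpoint, `b`
without, `c`/`d` the same in the comparator; `N = a+b+c+d` and
`E = (a+b)(a+c)/N` the count expected under independence.

**Comparator.** The default comparator is *all other deduplicated
reports in the loaded data*. Published FAERS analyses rarely state their
comparator and it changes the estimates materially (a within-screened
comparator gives much smaller denominators); both are implemented
(`comparator = "all"` / `"screened"`), the choice is recorded in the run
manifest, and the default is the one that uses all available information.

**ROR.** `ad/bc` with the 95% Wald interval
`exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`. Any zero cell triggers the
Haldane–Anscombe correction (+0.5 to all four cells) and a `corrected`
flag. The correction applies to the ROR only; IC and EBGM handle zeros
natively.

**BCPNN IC.** The modern shrinkage form
`IC = log₂((a+0.5)/(E+0.5))` with the closed-form lower credible bound
`IC025 = IC − 3.3(a+0.5)^(−1/2) − 2.0(a+0.5)^(−3/2)`. The original
full-Bayes variance formulation is out of scope; the shrinkage form is
the de facto standard and is what modern signal-detection practice means
by "BCPNN".

**MGPS / EBGM.** `a ~ Poisson(λE)` with the two-component gamma mixture
prior `λ ~ P·Gamma(α₁, β₁) + (1−P)·Gamma(α₂, β₂)` (shape/rate).
Marginally `a` is a mixture of negative binomials,
`dnbinom(a, size = α, prob = β/(β+E))`. The five hyperparameters are
fitted by maximizing the summed log marginal likelihood over the supplied
pairs with L-BFGS-B from the classic start point
(α₁, β₁, α₂, β₂, P) = (0.2, 0.1, 2.0, 4.0, 1/3), shapes and rates
box-constrained to [10⁻⁶, 50] and P to [10⁻⁶, 1−10⁻⁶]; mixture
log-densities are combined with log-sum-exp. Non-convergence (or an
all-zero count vector) falls back to the start-point prior with a warning
and `converged = FALSE`. One prior is fitted per analysis run, over *all*
drug × reaction-term pairs of the loaded data by default: eight
drug × endpoint tables cannot identify five hyperparameters, and fitting
across the whole table space is how the empirical-Bayes argument works in
the first place (`prior_pairs = "endpoints"` restricts it on request).

The posterior is again a two-component gamma mixture with weight `Q`
computed from the component marginal likelihoods (in log space).
`EBGM = 2^E[log₂ λ]` uses the digamma closed form
`E[ln λ] = Q(ψ(α₁+a) − ln(β₁+E)) + (1−Q)(ψ(α₂+a) − ln(β₂+E))`. EB05 and
EB95 solve posterior CDF = 0.05/0.95 by `uniroot` on the mixture CDF,
bracketed between the two component quantiles (the mixture CDF is
necessarily on opposite sides of the target at those points), with
absolute tolerance 10⁻¹⁰ on λ; tests verify the CDF at the returned
quantiles to 10⁻⁶ against numerical integration of the posterior
density. Pairs with `E = 0` (endpoint absent from cohort and comparator
alike) get `NA` posterior summaries and cannot be signals.

**Joint criterion.** A pair is a signal iff ROR ≥ 3 with CI lower bound
> 1, IC025 > 0 and EB05 > 2. No multiplicity adjustment is applied (the
three-method conjunction is itself the false-positive control in this
tradition); the number of tests run is recorded on the results table.

## Descriptive conventions

Percent denominators differ by block and are stored alongside every
count so each percent is re-derivable:

* age, sex, reporter, country: the cohort report count;
* serious outcomes: the *sum of outcome-category counts* — a report can
  carry several outcome codes and each is counted (death and
  life-threatening merge into one display category). This unusual
  convention is what reproduces the published outcome percentages
  (e.g. 906/(906+649+353+50+1) = 46.25%);
* endpoint frequencies: adverse-event totals (distinct report × PT pairs
  in the analysis view) — combined, per drug, and per drug × sex for the
  respective row types;
* concomitant drug rankings: counts are *reports* listing the dictionary
  drug (any role, substring on name and ingredient, levodopa and the
  cohort's own target excluded), but the percent denominator is the
  cohort's total drug-entry count. No printed convention reproduces the
  published top-5 percentages from report counts alone; the drug-entry
  total (≈6–7 entries per report) is the one denominator consistent with
  them, and it is documented here precisely because it is unusual.

Subgroup 2×2 comparisons use Pearson's chi-square without continuity
correction when all expected cells are ≥ 5 (the strict `< 5` rule decides
the branch; a table with minimum expected exactly 5 stays on chi-square),
otherwise Fisher's exact test, both two-sided; a zero margin returns a
degenerate p = 1. Display tables round half-up to two decimals; stars
follow the p < 0.05 (*) and p < 0.001 (***) convention. Cross-drug
endpoint comparisons report both the CI-overlap reading and the 2×2 test
p value; neither is privileged.

## The synthetic generator

`generate_synthetic_faers()` emulates the structures the pipeline
consumes: multi-drug, multi-PT reports with roles, routes, brand/generic
combination strings, per-drug indications, demographics with FAERS-style
unit codes and missingness, serious-outcome codes, and a configurable
fraction of reports re-emitted as a second case version. Drug presence is
independent Bernoulli per vocabulary entry; each PT is an independent
Bernoulli draw whose probability is multiplied by a planted relative risk
λ when an associated drug is present (capped at 1, with a message). When
several associated drugs co-occur, the *largest* λ applies — relative
risks do not compound, matching the "risk given exposure" reading of the
association list. The defaults mirror the study's qualitative pattern:
the benserazide partner loaded on dyskinesia and on-off, the carbidopa
partner on wearing-off, both elevated for freezing, at rates small enough
that background·λ ≤ 0.1.

Ground truth is recorded at generation time from the realized draws:
per-report eligibility flags with exactly the cascade's semantics, and
the realized (a, b, c, d) for every planted pair. Tests assert that the
screening cascade reproduces the eligible sets exactly and that counts
recomputed from the emitted files equal the recorded ones, for any seed.
`plant_flowchart()` switches the first target drug to deterministic
assignment so the cascade trace equals requested stage counts exactly.

What the generator does *not* emulate, and what passing tests therefore
do not show about real data: PT draws are independent given drugs (no
event–event correlation, no report-level multiplicity structure), drug
names are clean (no misspellings), reporting rates are stationary over
quarters, and there is no confounding by indication severity. The
generator validates estimators and plumbing, not epidemiology.

**Estimator recovery design.** `estimator_recovery_config(lambda)` is a
reduced design for measuring recovery of a planted λ through the full
pipeline: one association, the exposed product always suspect/oral/
PD-indicated, no excluding background terms, and a high-rate whitelisted
background symptom so the SOC stage retains essentially every report.
The last point is essential: with lossy SOC screening the exposed cohort
is *conditioned on having a whitelisted event*, which enriches endpoint
rates in the exposed arm only and biases the ROR upward by design — a
genuine property of SOC-restricted cohort screening worth knowing about,
not an estimator defect. The endpoint background probability is 0.03/λ
(constant 3% endpoint rate among exposed; rare-event regime where
OR ≈ rate ratio within a few percent), and the default size
`max(6000, 1600·λ)` keeps the *comparator* arm's expected endpoint count
above ~30 as well as the exposed arm's: below that the odds-ratio
estimator's small-sample skew (driven by E[1/c]) inflates its mean by
tens of percent at λ = 20.

## Problem sizes and runtimes

The test and acceptance runs use sizes chosen to make their statistical
assertions sharp while staying desk-scale: 1,000 simulated tables with
margins (200, 2,000) at event rate 0.1 for null Wald coverage (band
93–97%); 5,000 (a, E) pairs from a Gamma(2, 2) prior over E ∈ [0.5, 50]
for prior recovery (mean within 10%); 30 randomized (table, prior)
instances for the posterior-quantile oracle (10⁻⁶); 100 seeds per
λ ∈ {2, 5, 20} for pipeline recovery (CI coverage ≥ 90/100, mean within
15% over the first 50 seeds); 200 seeds of 2,000 reports for the null
median ROR; and a 20,000-report quarter for the workflow scripts.

## Known limitations

* The published RORs/ICs/EBGMs of the motivating comparison are not
  reproducible here: they require the full 2004Q1–2024Q2 FAERS download
  and depend on an unstated comparator population. The bundled reference
  tables carry the published *counts and tuples*, which validate the
  arithmetic conventions and the signal criterion, not the extraction.
* Only the post-2012 FAERS column layout is supported.
* The flat PT→SOC table is a miniature MedDRA stand-in (~70 terms); real
  analyses should substitute a licensed MedDRA export via the dictionary
  files.
* No stratification of E (age/sex/quarter) in the default MGPS path.
* Levodopa-equivalent dose effects, causality assessment and
  time-to-onset analyses are out of scope.
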