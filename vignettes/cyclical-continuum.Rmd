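---
title: "Cyclical continuum-of-care modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cyclical continuum-of-care modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carecycle)
```

## The model

A cyclical continuum arranges clinical *phases* on a closed cycle, each
phase holding one or more *elements of care*: measurable states, exposures,
or interventions. Unlike a hierarchical cascade, no element is the
denominator for the others — useful when the cohort was selected on a
mid-cycle condition (here, a musculoskeletal infection) rather than on the
first risk factor, and when competing or recurrent outcomes (antibiotics,
sepsis, amputation) belong in one picture.

Each element is compared across population strata on the *relative* scale.
For element \(k\) with indicator \(Y_k\), one multivariable logistic
regression is fit:

\[
\operatorname{logit} P(Y_k = 1) =
  \beta_0 + \sum_g \beta_g \,[\text{stratum}=g] +
  \beta_{\text{age}}\,\text{age} + \beta_{\text{sex}}\,[\text{male}],
\]

with strata dummy-coded against a reference. The reported quantities are
\(\mathrm{OR}_g = e^{\beta_g}\), the two-sided Wald interval
\(e^{\beta_g \pm z_{1-\alpha/2}\mathrm{SE}(\beta_g)}\), and the Wald
p-value. A stratum-element result is flagged *significant* when its
interval excludes 1.00; no multiple-testing correction is applied
(\(\alpha = 0.05\) per comparison, the convention of the underlying
methodology).

**Reference selection.** The reference stratum is the group with the lowest
*crude* odds (TRUE/FALSE count ratio) of the cycle's *index element*
(diabetes mellitus in the default spec). Crude rather than adjusted odds
make the choice deterministic before any model is fit; ties break
lexicographically. Per-stratum *adjusted* odds are available behind
`reference_method = "adjusted"` for sensitivity analyses. A stratum in
which every patient carries the index element has infinite crude odds and
can never be selected.

**Covariates and missingness.** Age enters linearly in years — the minimal
reading of "adjusted for age and sex" — and sex as a female/male binary.
Rows with missing covariates or a sex value outside that binary are dropped
per model with a logged count (complete-case analysis); imputation is out
of scope.

**Separation.** With five strata, eight elements, and strata as small as
2–3% of the cohort, zero-event cells occur. Fits where a stratum has zero
(or all) events, where IRLS fails to converge, or where a coefficient or
its standard error has blown up are flagged `degenerate` and reported with
`NA` estimates — never as finite numbers. There is no automatic penalized
fallback; a Firth-type fit is a deliberate non-feature of this version so
that reported numbers always mean plain maximum likelihood.

## Phenotyping rules

An element rule is a disjunction of criteria: the element is TRUE iff at
least one criterion holds.

* **Code criteria** match normalized codes (dots stripped, upper-cased) by
  prefix within one code system (ICD-9, ICD-10, or procedure); `NULL`
  prefixes mean "any code of the system" (used for *any surgical
  procedure*). Amputations are identified by an explicit `is_amputation`
  flag on procedure rows because amputation code systems vary across sites;
  an anatomic-site taxonomy is deliberately not modeled.
* **Lab criteria** aggregate all of a patient's results for an analyte
  (`max`, `min`, or `any`) and compare against a threshold — e.g. maximum
  HbA1c ≥ 6.5% for diabetes. Units must match the criterion exactly
  (HbA1c in `%` only); rows in other units are skipped with a warning
  rather than silently converted, since unit conversion is a correctness
  hazard.
* **Medication criteria** match drug-class labels case-insensitively, with
  route-based exclusions (systemic antimicrobials exclude `topical`).
  Antibiotic use counts a prescription at any time in the record; no
  episode restriction is applied in this version.
* **Composite criteria** are TRUE iff at least `min_count` member elements
  are TRUE. Members must be atomic, so one topological pass — atomic
  elements first, composites second — is always sufficient. The default
  cycle's *multiple infections* element is 2-of-{osteomyelitis, septic
  arthritis, infectious myositis}; the latter two are *helper elements*:
  evaluated for the composite and the anchor but not cycle axes, so the
  element matrix has exactly one column per cycle element.
* **Time windows** are anchored at the *index infection date* — the
  earliest diagnosis among the spec's anchor elements — and are inclusive
  at both ends. "Three months" is fixed as 90 days: calendar-month
  arithmetic is locale-ambiguous, 90 days is deterministic. Patients with
  no anchoring diagnosis fail cohort inclusion and are excluded with a
  logged count before the matrix is built.

The shipped ICD prefix lists and drug-class vocabularies are
**illustrative**. They make the default model runnable and testable, but a
site analysis must substitute curated code sets via the YAML spec.

## Visualization conventions

The radar figure places one axis per cycle element, equally spaced
(360°/n), the first element at 12 o'clock, proceeding clockwise — reading
order for a clinical cycle. The radial scale is the natural log of the OR,
so OR = 1 is a ring (dashed, visually distinct) and reciprocal ORs are
symmetric about it. Radial limits are symmetric about 0 and padded outward
to the nearest power-of-two ring, with tick rings at
OR ∈ {0.25, 0.5, 1, 2, 4, 8} intersected with the range (extended by
further powers of two only when estimates fall outside). All panels of one
figure share the same limits and ticks, so polygons are comparable across
strata.

Degenerate estimates *break* the polygon into open segments rather than
plotting at the OR = 1 radius, which would fabricate a null effect.
Confidence intervals are not drawn by default — significance is marked by
asterisks on axis labels — because depicting statistical error on cyclical
maps is itself an open methodological question; a per-vertex radial CI
whisker can be added by post-processing `tidy()` output if needed.

The SVG writer emits fixed-precision coordinates and no timestamps, so
identical estimates produce byte-identical files; this is load-bearing for
reproducibility checks and is verified in the tests, along with vertex
geometry recomputed from the layout to within half a pixel.

## The synthetic-cohort generator

The generator emulates a single-center hospital cohort of adults with
musculoskeletal infections. Its packaged defaults are the published shape
of such a cohort: five race/ethnicity strata with proportions
0.402/0.350/0.177/0.045/0.026, per-stratum age means 52.3/56.3/50.9/54.6/
53.4 years (SDs 15.8/14.3/14.6/16.3/13.7, normal truncated at 18 by
rejection sampling), and a 31.7% female fraction applied uniformly since
sex did not differ across groups in the emulated setting.

Per element, truth is a logistic model. Stratum log-ORs in the
`sim_config_table2()` scenario are the natural logs of published adjusted
point estimates for the eight elements — an *emulation scenario* for demos
and recovery studies, not a reproduction of any study, whose patient-level
data are not public. Reference-stratum target prevalences are not published
anywhere, so they were chosen once as clinically plausible values for an
inpatient MSK-infection cohort — diabetes 0.30, peripheral vascular disease
0.06, osteomyelitis 0.45, multiple infection types 0.10, sepsis 0.25,
systemic antibiotics 0.80, surgery within 90 days 0.35, amputation 0.08 —
and are not tuning knobs. Covariate effects are small positive log-ORs per
year of age for age-graded conditions (0.015–0.04) and modest male excesses
(0–0.2), reflecting the male predominance of MSK infections and
amputations.

Three design points matter for correctness:

* **Intercept calibration.** Element intercepts are found by bisection so
  that the mean inverse-logit of the linear predictor over the *reference
  stratum's realized covariate sample* equals the target prevalence
  (tolerance 10⁻⁹ on the mean; the mean is monotone in the intercept, so
  the root is unique). The calibration contract is exact on the
  conditional scale; the realized prevalence then differs only by binomial
  noise.
* **Containment by construction.** Amputation implies surgery in the
  phenotype rules ("any surgical procedure, including amputation"), so the
  generator draws amputation *inside* surgery by conditional thinning with
  probability \(q(x) = \mathrm{expit}(\eta_A(x)) / \mathrm{expit}(\eta_S(x))\).
  Both marginals remain exactly logistic — so parameter recovery is clean
  for both elements — and containment is structural. Feasibility
  (\(q \le 1\)) is verified at simulation time and infeasible
  configurations are rejected.
* **Exact emission.** TRUE elements are materialized as raw dated events
  that the default rules recover *verbatim* (one diabetes mechanism chosen
  at random among code/lab/medication; a second infection type only when
  the multiple-infections truth demands it; surgical events inside the
  0–90-day window), plus decoy events that must *not* flip anything:
  normal-range HbA1c results, topical antimicrobials, out-of-window
  procedures. Emission is noise-free in this version — no miscoding or
  missingness processes — so "phenotype equals truth for 100% of patients"
  is a meaningful oracle. Consequently, passing end-to-end tests
  demonstrates internal consistency of rules, generator, and estimator;
  it does not demonstrate robustness to real-world coding noise.

Elements are conditionally independent given covariates by default; an
optional shared patient-level normal frailty on every linear predictor
(`frailty_sd > 0`) induces positive dependence (e.g. diabetes–amputation
clustering). Real elements are plainly correlated, but no joint model is
identifiable from published marginal ORs, so dependence is opt-in and the
recovery claims hold under the generator's own model.

All randomness flows through R's default generator from the single config
seed, so a seed reproduces cohorts byte-identically; replicate \(i\) of a
recovery study uses `seed + i`.

## Numerical choices

* Logistic fits use IRLS with a relative deviance-change tolerance of
  10⁻¹⁴ (at most 100 iterations). The tight tolerance is deliberate:
  deviance error ε leaves coefficient error of order √ε, and the package
  asserts agreement with closed-form 2×2 contingency results to 10⁻⁶
  relative, which a looser deviance tolerance does not deliver on sparse
  tables. The extra iterations are negligible (IRLS is locally quadratic).
* Degeneracy flags: non-convergence, zero or all events in a stratum,
  |log OR| > 15, or SE > 50.
* Ties in reference selection break lexicographically by stratum label;
  ordering of all tables is canonical (sorted), so shuffled inputs yield
  identical objects.
* Percentages and ages in descriptives are rounded to one decimal at the
  *rendering* layer only (print/CSV); objects keep full precision so
  round-trips are lossless at the documented precision.

## Validation strategy and problem sizes

The test suite validates each stage against an oracle independent of the
implementation path: the cross-product ratio and closed-form Wald interval
for 2×2 designs; generator ground truth for phenotyping; recomputed polar
coordinates for the SVG; and simulation for the estimator's sampling
behavior. The recovery study uses cohorts of n = 2000 over 200 replicates
and the null (all stratum log-ORs zero) scenario at the same size — large
enough for meaningful coverage and type-I-error assessment while keeping a
full run in minutes on one core.

## Known limitations

* **Sparse-cell bias conditional on estimability.** In the smallest
  stratum (2.6% of the cohort) with a strongly protective true OR, a
  replicate's fit frequently separates (zero events) and is flagged
  degenerate. The mean ML log-OR *conditional on non-separation* is then
  intrinsically biased — the replicates that would pull the mean down are
  exactly the ones that cannot be estimated — and the recovery study shows
  this cell exceeding the 3-Monte-Carlo-SE bias band that all well-populated
  cells satisfy. This is a property of plain maximum likelihood plus honest
  degeneracy flagging, not of the implementation; a penalized (Firth)
  estimator would trade it for shrinkage bias and is out of scope for this
  version.
* Elements' real-world dependence structure is not modeled beyond the
  optional shared frailty.
* Phenotyping has no NLP, no code-set inference, and exact-label site
  matching only; lab units are not converted.
* The binary sex adjustment mirrors the source regression; records outside
  the binary are retained in data but excluded from models, with counts
  logged.
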