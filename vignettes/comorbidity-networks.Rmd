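---
title: "Comorbidity network analysis of discharge records: models and design choices"
author: "comorbnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity network analysis of discharge records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbnet)
```

comorbnet implements a complete phenotypic-disease-network (PDN) analysis of
comorbidity around an index condition — by default ischemic heart disease
(IHD), ICD-10 I20–I25 — from administrative hospital discharge records
(HDRs). This vignette explains the statistical model at each stage, the
parameters that matter and their defaults, the synthetic-data generator used
for validation, and the design choices made where the methodology was
genuinely open.

## From discharge rows to patient phenotypes

An HDR is one row per hospitalization: demographics, admission/discharge
dates, hospital level, a death flag, and one primary plus up to 15
secondary ICD-10 diagnoses. Three reductions take it to the analysis unit:

1. **Three-character aggregation.** Every diagnosis is truncated to its
   3-character category (`I25.102` → `I25`), the granularity at which
   administrative coding is comparable across hospitals.
2. **Chapter and chronicity filters.** Codes from the
   injury/external-cause/health-services chapters (first letter S, T, V, W,
   X, Y, Z) are not diseases and are dropped. At three characters the
   sliver T89–T99 cannot be separated from the injury block T00–T88 by the
   letter alone, so the whole T chapter is excluded; this is documented
   behaviour, not an oversight. Acute conditions are removed with a
   chronic-condition code list. The shipped list
   (`defaultChronicCodes()`) is a *synthetic stand-in* assembled from
   well-known chronic 3-character categories; real analyses should supply
   the licensed chronic-condition indicator their jurisdiction uses — every
   function takes the list as an argument.
3. **Per-patient union.** A patient's phenotype is the union of their
   retained codes over all hospitalizations in the study window. Burden is
   therefore a period quantity; no per-admission weighting is applied.
   Conflicting sex values across a patient's records abort profile
   construction (matching validity depends on sex), while malformed rows
   are counted into a rejection report rather than silently dropped.

The result is a `PatientProfiles` object: a sparse patients x codes
incidence matrix plus matching covariates (sex, birth year, age and age
group at the first record, latest discharge date and its hospital level,
death flag).

## Cohort: cases and 1:1 matched controls

Cases are patients with any I20–I25 code, aged ≥ 35, with no death
recorded. Index position is not required: the data source does not
guarantee that the index condition is the primary diagnosis, so "a
diagnosis of I20–I25" is read as any position.

Controls are matched 1:1 without replacement on birth year (± 2 years),
sex (exact), hospital level (exact), and discharge date. Matching is
greedy and randomized: cases are shuffled under the matching seed, and each
case draws one control uniformly from the remaining eligible pool. Greedy
random matching is the standard reading of "randomly selected" control
matching; optimal bipartite matching would maximize the match rate but
changes the estimand subtly and is out of scope. Cases with no eligible
control are reported, with an audit of which single criterion blocked each
one. Controls must be free of the index condition over the whole window.

The discharge-date tolerance defaults to the same calendar day in
`matchCriteria()`, which is the strict interpretation; at desk-scale sample
sizes exact-day matching is infeasible, so the pipeline default widens it
to ± 30 days. Both are configuration, not behaviour changes.

## Per-condition statistics

For each code with prevalence ≥ 1% in the case arm (the usual reliability
floor for rarely diagnosed diseases; boundary inclusive, and the index
codes themselves excluded):

* **Prevalence** with a Wald interval `p ± z·sqrt(p(1−p)/N)`. At the
  sample sizes this method targets (10^5–10^6 per arm) Wald and Wilson
  intervals agree to the printed digit; Wilson is available via
  `method = "wilson"` for small arms.
* **Odds ratio** from the case/control 2×2 table, with the Woolf
  log-normal interval and a normal-score p-value;
  the Haldane–Anscombe 0.5 correction is applied only when a cell is zero.
  An exact-conditional interval (Fisher) is used as an *oracle* in the
  tests, never as the implementation.
* **Bonferroni screen**: significance means `p < alpha/m` with `m` the
  length of the case arm's comorbidity list, recomputed per dataset rather
  than hard-coded to any published count.
* **Enrichment**: OR > 1, Bonferroni-significant, and case prevalence at
  least 1.5 times control prevalence ("increased over 0.5 times", read as
  ≥ 1.5 with the boundary included). A condition absent from controls
  has an infinite ratio and is enriched whenever the OR conditions hold.

Sex-specific conditions (prostate hyperplasia, menopausal disorders, ...)
are computed over the full matched denominator by default. A published OR
for such a condition may instead use a sex-restricted denominator; since
that choice is rarely documented, the package leaves it to the caller
(subset the profiles by sex first) instead of guessing.

## The OER network

Comorbidity strength of a disease pair is the observed-to-expected ratio

$$\mathrm{OER}_{ij} = \frac{C_{ij}\,N}{C_i\,C_j},$$

the ratio of observed co-occurrence prevalence to the product of the
marginal prevalences: above 1 means co-occurrence beyond chance, below 1
mutual exclusivity. A pair becomes an edge when its OER exceeds 1 *and*
the lower bound of its confidence interval (99% by default) exceeds 1.
Edge weight is the OER; nodes are the arm's full comorbidity list, with
codes lacking any significant edge kept as isolates (they still count in
the density denominator — density is a statement about the comorbidity
universe, not only about connected diseases).

**The OER interval.** The interval is log-normal,
`exp(ln OER ± z·sigma)`. The default sigma is Katz-style,
`sqrt(1/C_ij − 1/N + 1/E − 1/N)` with `E = C_i C_j / N`; a Poisson
approximation `1/sqrt(C_ij)` is selectable via `sigma = "poisson"`. The
Katz form treats the observed count and its expectation as independent
Poisson-binomial quantities; because the expectation shares the margins
with the observed count they are positively correlated, so the interval is
mildly conservative. The package's null simulations measure a false-edge
rate of well under 1% at the 99% gate — calibrated in the direction that
protects the edge set. A pair with `C_ij = 0` has no finite log interval
and can never be an edge.

**Metrics.** Five structural metrics are reported. Degree, average
neighbor degree and density are the standard unweighted quantities.
Closeness is normalized hop-distance closeness computed within each
connected component and scaled by the component's share of nodes
(isolates get 0). The diameter, by contrast, is weighted: edge length is
`1/OER`, so stronger comorbidity means a shorter path, and the diameter is
the largest shortest-path distance on the largest component. The split —
hop distances for closeness, `1/OER` lengths for the diameter — follows
what reproduces published values of these metrics on dense comorbidity
networks (closeness near `0.8` and non-integer sub-3 diameters on a
~78%-dense 71-node graph are only consistent with exactly this
combination). Both choices are implemented explicitly rather than left to
library defaults.

**Display filtering.** Dense PDNs are unreadable; `p90EdgeFilter()` keeps
edges whose OER strictly exceeds the 90th percentile (linear-interpolation
quantile) of the network's edge OERs and reports the threshold. With fully
tied weights, nothing exceeds the percentile and the filtered network is
edgeless — the strict inequality is deliberate.

## Communities

Communities are found by the fast-unfolding (Louvain) algorithm on the
OER-weighted graph, at resolution 1 (classical modularity). The algorithm
is greedy with randomized tie-breaking, so a seed is mandatory and
recorded; repeated runs with one seed are identical. The coarsest (final)
level is returned: it is the layer with the highest modularity among the
algorithm's clustering levels, which matches the usual reporting
convention. Partition quality is the weighted Newman–Girvan modularity

$$Q = \sum_c \left[\frac{W_c}{W} - \left(\frac{S_c}{2W}\right)^2\right].$$

## Stratified comparison

Networks are rebuilt per stratum — sex (male/female) or the fixed age bins
35–59, 60–69, 70–79, 80+ — each with its own ≥ 1% comorbidity list.
Metric comparison between two strata uses a paired t test over the nodes
common to both networks, one value per node per metric; for more than two
strata, one-way ANOVA over per-node values grouped by stratum. The paired
reading of "pair-wise t test" is the natural unit when the shared objects
are diseases; an unpaired Welch option is exposed because the published
convention is not always stated. With fewer than 3 common nodes the test
is reported as NA rather than run.

Sex-dominant disease pairs: among comorbidities present in both strata,
pairs significant in *both* networks whose OER ratio in either direction
is at least 1.2 are emitted, labeled with the dominant stratum. A pair
absent from one network has no defined ratio, so significance in both arms
is a precondition, and by default only cross-chapter pairs ("different
disease systems") are considered; both are configurable.

## The synthetic generator and what it validates

Real HDR databases are access-restricted, so the package ships a generator
whose defaults define the validation conditions, with ground truth exposed
for every planted feature:

* **Prevalence spectrum:** log-uniform on [0.01, 0.50] by default — most
  conditions at a few percent, a few up to 50% — matching the heavy-tailed
  spectra of chronic-condition prevalence in discharge data.
* **Planted OER blocks:** a latent-block mixture. Each patient joins block
  `b` with propensity π; members' diseases fire with probability βp when
  the patient is in the block and `p(1 − πβ)/(1 − π)` otherwise, so the
  marginal prevalence is exactly `p` and the within-block pair OER is
  exactly `πβ² + (1 − πβ)²/(1 − π)`. Solving for a target θ gives the
  closed form `β = 1 + sqrt((1 − π)(θ − 1)/π)`; the default propensity is
  `0.5/θ`. One mechanism therefore yields calibrated pairwise OERs *and*
  natural planted communities — the reason it was chosen over pairwise
  copulas. Targets above the attainability bound `1/max(p_i, p_j)` (or
  whose boost would push a member probability past 1) fail fast with an
  error naming the offending disease, rather than silently clamping.
* **Case enrichment:** cases multiply designated diseases' prevalences by
  configurable factors (clamped at 0.95 with a warning).
* **Plumbing noise:** acute and excluded-chapter codes are injected into
  records, sex encodings are deliberately mixed, and codes carry dotted
  extensions, so the parsing/filter path is always exercised. Records per
  patient are `1 + Poisson(1)`, with enough records that scattering never
  overflows the 16 diagnosis slots.
* **Determinism:** all randomness flows from the single config seed;
  identical configs produce byte-identical tables.

`makePaperlikeScenario()` is the shipped reference scenario: 70 diseases
log-spaced from 50% down to 1%, two 8-disease blocks planted in the case
arm at OER 3 and 2.5, and 20 enriched diseases whose common multiplier is
set *analytically* so the expected case/control burden ratio is 1.5 — the
"50% larger comorbid burden" regime. Nothing in the scenario is fitted to
any measured outcome; the burden multiplier solves
`sum(case prevalence) = 1.5 * sum(control prevalence)` in closed form.

**What passing tests do and do not show.** The generator produces
exchangeable patients with block-structured dependence. Real discharge
data additionally have coding drift over time, hospital-level coding
styles, age- and sex-dependent prevalence, and dependence structures far
richer than disjoint blocks. Recovery of planted OERs, communities and
enrichment therefore validates the *estimators and pipeline wiring*, not
the clinical generalizability of any particular finding.

## Numerical and degenerate-input choices

* Prevalence-ratio boundaries are computed as `(a/c)·(N0/N1)` so an exact
  1.5 is not blurred by floating point.
* `OER` with a zero marginal is an error (the pair is not evaluable), not
  a silent NA; `C_ij = 0` gives NA interval bounds and never an edge.
* Empty graphs: average degree and density are 0; a singleton component
  has diameter 0; isolates get closeness and neighbor-degree 0.
* Matching with no eligible control reports the case as unmatched; an
  empty cohort summarizes to zeros.
* Percentile filtering uses R's default type-7 (linear interpolation)
  quantile.
* The pipeline derives per-stage seeds from the top-level seed by a fixed
  affine map modulo 2^31 − 1, so stage results are independent of each
  other's consumption of the random stream.

## Problem sizes used in the validation suite

The shipped tests run the generator at 10,000–100,000 patients (100,000 —
i.e. ~50,000 per arm — for community recovery and calibration checks, 200
replicates of 10,000 for null calibration of the edge gate, 20 seeds of
50,000 for OER recovery, 10 seeds of 20,000 for the burden-ratio regime).
These sizes were chosen so each check's Monte-Carlo error is comfortably
below the property margin being asserted while the whole suite stays
interactive.

## Known limitations

* The chronic-condition list shipped is a stand-in; results on real data
  are only as good as the licensed indicator supplied.
* ORs are unadjusted (matching handles confounding by design); no
  multivariable modelling, survival, or cost outcomes.
* The network is undirected and atemporal: no causality or disease
  trajectory can be inferred from an OER edge.
* Greedy matching does not maximize the match rate; unmatched cases are
  reported and should be examined for selection effects.
* ICD-10 semantics beyond the chapter letter are not modelled in the
  generator; synthetic codes exercise the plumbing, not clinical content.
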