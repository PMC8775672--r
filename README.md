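# comorbnet

Phenotypic disease network (PDN) analysis of comorbidity from hospital
discharge records, built for epidemiologists working with administrative
inpatient data. The package takes long-format discharge-record tables (one
row per hospitalization, primary + up to 15 secondary ICD-10 diagnoses) and
produces, around an index condition (by default ischemic heart disease,
I20–I25):

* patient-level chronic phenotype profiles (3-character ICD-10 codes,
  chapter and chronicity filters, per-patient union over the study window);
* a 1:1 matched case–control cohort (birth year ± 2, sex, discharge date,
  hospital level; greedy randomized matching without replacement);
* per-condition prevalence (Wald CI), odds ratios (Woolf CI,
  Bonferroni-corrected at `0.05/m`) and an enrichment screen (OR > 1,
  significant, case prevalence ≥ 1.5× control);
* the comorbidity network itself, with per-pair observed-to-expected ratio

  `OER_ij = C_ij · N / (C_i · C_j)`

  as edge statistic, an edge kept when its 99% CI lower bound exceeds 1;
  the five standard network metrics (degree, closeness, average neighbor
  degree, weighted diameter with 1/OER edge lengths, density), a P90
  strongest-edge filter, and fast-unfolding (Louvain) community detection;
* sex- and age-stratified networks with paired-t/ANOVA metric comparisons
  and sex-dominant disease pairs (OER ratio ≥ 1.2);
* a calibrated synthetic discharge-record generator with planted ground
  truth (prevalence spectrum, OER blocks, communities, enrichment), so the
  entire pipeline is testable without access-restricted patient data.

Data objects follow Bioconductor idioms: S4 classes (`PatientProfiles`,
`MatchedCohort`, `PDN`, `CommunityPartition`) with validity, accessors and
`show()` methods; graphs are `igraph` objects exported as GraphML.

## Worked example

```r
library(comorbnet)

cfg <- runConfig(
  scenario = makePaperlikeScenario(n_patients = 10000, seed = 42),
  seed = 1)
rep <- runPipeline(cfg)
print(rep)
```

```
[comorbnet] simulating discharge records (seed 42)
[comorbnet] 21393 records parsed, 0 rejected
[comorbnet] 10000 patient profiles
[comorbnet] 4774 cases; 3743 matched pairs; 1031 unmatched
[comorbnet] 68 case / 69 control comorbidities; mean burden 13.29 vs 8.89
[comorbnet] case PDN: 56 edges; control PDN: 0 edges
comorbnet pipeline report (seed 1)
  records: 21393 (0 rejected)
  cohort: 3743 matched pairs
  burden: 13.29 (case) vs 8.89 (control)
  case PDN: 68 nodes / 56 edges, density 0.025, Q = 0.496 (54 communities)
  control PDN: 69 nodes / 0 edges, density 0, Q = 0 (69 communities)
```

The scenario plants two 8-disease blocks (target OERs 3 and 2.5) in the
case arm and enriches 20 diseases so cases carry ~1.5× the control burden:
the report shows exactly that regime — heavier case burden (13.29 vs 8.89),
a case network whose 56 significant edges are the planted within-block
pairs (2 × 28), and an edgeless control network, since control diseases are
independent. The condition table ranks enriched codes by OR:

```r
st <- rep$condition_stats
head(st[order(-st$or),
        c("code", "prevalence_case", "prevalence_control", "or", "enriched")], 3)
```

```
  code prevalence_case prevalence_control    or enriched
1  A00           0.913              0.492 10.79     TRUE
2  A22           0.857              0.483  6.42     TRUE
3  A43           0.814              0.450  5.34     TRUE
```

With `out_dir` set, `runPipeline()` writes matched pairs, condition
statistics, edge tables, GraphML networks (full and P90-filtered),
community memberships, and a `report.json` with every threshold and seed.
Real data enter through `parseHdrTable(path, hdrDialect(...))`, with a
column-mapping dialect for non-canonical files, and a chronic-condition
code list supplied via `chronic =` (the bundled list is a synthetic
stand-in, see `?defaultChronicCodes`).

A thin command-line wrapper is available at
`inst/scripts/pdn_pipeline.R`.

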