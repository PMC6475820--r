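# querysignal

Event-anchored analysis of health-related search-query logs.

`querysignal` is an infodemiology toolkit for per-user search-engine
query streams. Its motivating use case is celiac disease and the
gluten-free diet: celiac presents with such a heterogeneous set of
intestinal and extraintestinal symptoms that case finding is hard, and
search logs let us observe what individuals were querying *before* the
moment they first showed interest in the condition. The package builds
the analysis end to end:

- **Ingestion** of tab-separated query logs (user id, ISO-8601
  timestamp, query text, optional zip code) with text normalization,
  itemized rejection reporting, and deterministic stable ordering.
- **Cohort construction**: a celiac-related query (CRQ) is any query
  containing a word starting with "celiac" or "gluten"; users enter the
  cohort if their *first* CRQ falls in an index month, they have
  observable history before it, and a washout period (default 9 months)
  contains no CRQ. Users are labelled *passing* (CRQs on one calendar
  day) or *sustained* (more than one day), and flagged for diagnostic
  indicator phrases and first-person self-identification.
- **The query ratio (QR)**: for each concept in a symptom or condition
  lexicon, the pooled count of matching queries in the 14 days before
  each member's first CRQ divided by the pooled count in the 14 days
  after it:

  `QR(c) = n_before(c) / n_after(c)`

  with half-open windows `[t0 − w, t0)` and `(t0, t0 + w]` that both
  exclude the index query. QR > 1 marks concepts searched more in the
  run-up to the first CRQ. Event-anchored **temporal profiles** show the
  concept's per-day query share against its overall share.
- **Dietary shift**: recipe queries are mapped to dishes and their
  ingredients, and ranked by the smoothed log-ratio
  `log((n_after + 0.5)/(n_before + 0.5))` across the same windows.
- **Discrimination check**: users represented by pre-CRQ counts of every
  symptom/condition concept, evaluated with 10-fold cross-validated AUC
  under ordinary least squares or a 50-tree random forest.
- **A synthetic log simulator** with planted ground truth (adopter
  fraction, passing/sustained mixture, pre-CRQ rate multipliers,
  post-CRQ gluten-free recipe shift, self-identification), so the whole
  pipeline is testable without access to any proprietary search log.

Real search logs are proprietary; the package therefore validates by
*parameter recovery*: quantities it estimates on simulated data must
match what the simulator planted, within Monte-Carlo error.

## Worked example

Simulate a log with a planted two-fold pre-CRQ elevation of diarrhea
queries, build the cohort, and rank symptoms by query ratio:

```r
library(querysignal)

cfg <- sim_config(n_users = 1200, background_rate = 1,
                  adopter_fraction = 0.5, sustained_fraction = 0.07,
                  pre_window_multipliers = c(diarrhea = 2, headache = 1.5),
                  seed = 42)
sim <- generate_logs(cfg)
sim
#> <sim_result> 363846 records from 1200 users (584 adopters, 37 sustained)

cohort <- build_cohort(sim$records, cohort_config())
cohort
#> <cohort> 584 members of 1200 users
#>   excluded: no_history=0, no_index_crq=616, washout_crq=0

cohort_summary(cohort)
#> <cohort_summary> 584 users with >=1 CRQ
#>   passing interest:   547 (94%)
#>   sustained interest: 37 (6%)
#>   indicator-positive among sustained: 0 (0%)
#>   self-identified among sustained: 0 (0%)
#>   self-identified overall: 4 (0.68%)

qr <- query_ratio_table(cohort$members, sim$records, cfg$symptom_lexicon,
                        min_support = 10, span = cfg$span)
rank_concepts(qr, top_k = 5)[, .(rank, concept_id, n_before, n_after,
                                 qr = round(qr, 2))]
#>     rank   concept_id n_before n_after    qr
#> 1:     1     diarrhea       45      26  1.73
#> 2:     2 exophthalmos       30      18  1.67
#> 3:     3  steatorrhea       28      19  1.47
#> 4:     4      anxiety       32      22  1.45
#> 5:     5     headache       37      28  1.32
```

The planted concept tops the ranking: its estimated QR of 1.73 carries a
delta-method standard error of about 0.43 at these pooled counts, so it
is consistent with the planted multiplier of 2 — and the runners-up
illustrate why `min_support` and larger cohorts matter before reading
anything into a single ratio.

The whole pipeline (simulate → ingest → cohort → ratios → profile →
dietary shift → classifier, with a machine-readable run report) runs
from one configuration:

```r
run_pipeline(system.file("extdata", "pipeline-demo.yaml",
                         package = "querysignal"),
             out_dir = "demo-run")
```

A thin command-line wrapper with per-stage subcommands is installed at
`system.file("scripts", "querysignal", package = "querysignal")`.

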