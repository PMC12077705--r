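# gliopfs

Automated progression-free survival (PFS) endpoints for glioblastoma from
electronic-health-record (EHR) data.

PFS — the time from the end of chemoirradiation (CRT) to disease
progression — is the endpoint biomarker studies need and public GBM
datasets almost never have, because the clinical standard (RANO criteria
applied by a multidisciplinary team over the whole chart) is manual and
subjective. `gliopfs` derives PFS dates from three EHR modalities that *are*
routinely available, and compares them against a clinical-standard date:

* **Prescriptions** — dexamethasone orders ≥ 1 month after CRT end are
  collapsed into a single taper course from the first largest-dose order to
  the last smallest-dose order; the course start dates progression.
* **Radiology reports** — rule-based NLP of post-treatment brain-MRI
  reports: stem matching of progression/stability terms, ConText-style
  modifiers (negated, historical, hypothetical, family, and a custom
  *surgical* context for pseudoprogression), re-categorisation, and a
  one-to-one frequency rule: a document calls progression iff unmodified
  progression terms strictly outnumber stability terms
  (ties — surgical counts included on the stability side — never call
  progression). The first progression report dates progression.
* **Tumor volumes** — each post-CRT contrast-enhancing (CE) volume `V_t` is
  compared to the fixed post-surgery, pre-CRT baseline `V_0` via the
  relative change `r_t = V_t / V_0`; the earliest scan with `r_t ≥ 1.05`
  (a ≥ 5% increase, inclusive) dates progression.

Endpoint distributions are compared with Table-style descriptives, paired
differences (negative = automated date earlier than clinical), a
Kruskal–Wallis omnibus test over patients progressing by all methods,
exact Wilcoxon signed-rank tests with Bonferroni correction (m = 6), ±2
month agreement fractions, and OLS trendlines.

Because real cohorts of this kind are protected health data, the package
includes a seeded synthetic EHR generator (`simulate_cohort()`) with known
ground truth — lognormal right-skewed PFS, lagging steroid tapers,
template-built surveillance reports every 2–4 months, CE volume
trajectories with a configurable volume-silent fraction — so the entire
pipeline is testable end to end. See the vignette
(`vignettes/deriving-pfs-endpoints.Rmd`) for the model, parameters, and
design decisions.

## Worked example

```r
library(gliopfs)

sim <- simulate_cohort(cohort_config(n_patients = 92, seed = 1))
fit <- derive_pfs(sim$cohort)
fit
#> PFS endpoint derivation
#>   cohort: 92 eligible patients
#>   clinical   progressed 91/92 (99%)
#>   steroid    progressed 51/92 (55%)
#>   nlp        progressed 66/92 (72%)
#>   volumetric progressed 52/92 (57%)

summary(fit)
#> PFS endpoints over 92 eligible patients
#>
#> Per-method descriptive statistics (months):
#>   clinical   99% progressed (n=91)  mean 16.8  sd 33.2  median 4.7  range 0.3-218.1
#>   steroid    55% progressed (n=51)  mean 25.1  sd 33.2  median 12.9  range 1.1-189.2
#>   nlp        72% progressed (n=66)  mean 10.1  sd 14.2  median 5.7  range 2.1-70.7
#>   volumetric 57% progressed (n=52)  mean 14.6  sd 18.1  median 6.8  range 2.1-78.8
#>
#> Difference from clinical standard (months; negative = earlier):
#>   steroid    mean 5.0  sd 6.9  median 4.8  range -6.0-22.2 (n=51)
#>   nlp        mean -1.7  sd 8.5  median 1.0  range -33.7-7.1 (n=66)
#>   volumetric mean -0.6  sd 3.2  median 0.7  range -9.9-3.5 (n=52)
#>
#> Agreement within 2 months of clinical date:
#>   steroid    22%
#>   nlp        44%
#>   volumetric 58%
#>
#> Kruskal-Wallis (complete cases, n=21 per method): H = 1.8, df = 3, p = 0.62
#>
#> Pairwise Wilcoxon signed-rank (Bonferroni m = 6):
#>   steroid    vs clinical   W = 189.0, p = 1.5e-05 (adj 9.2e-05, n=50)
#>   ...
```

Reading this: almost every patient progresses under the clinical standard,
but each single modality detects only 55–72% of the cohort; the steroid
method runs ~5 months *late* (tapers follow the clinical call), while
report NLP and volumetrics run slightly *early* (radiographic change
precedes consensus) — the timing signature the comparison protocol is
built to expose. Every determination carries evidence
(`fit$evidence[["P001"]]$nlp`, etc.): the taper course, the per-report
term audit, or the full ratio series.

`plot(fit)` draws the boxplot/scatter panel with OLS trendlines;
`residuals(fit)` returns per-patient differences from the clinical date.
A thin CLI over the same functions lives at `inst/cli/gliopfs.R`
(`simulate`, `derive`, `compare` subcommands).

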