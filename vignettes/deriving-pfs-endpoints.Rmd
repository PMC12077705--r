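---
title: "Deriving progression-free survival endpoints from glioblastoma EHR data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving progression-free survival endpoints from glioblastoma EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliopfs)
```

## The problem

Progression-free survival (PFS) — here, months from the last day of
chemoirradiation (CRT) to disease progression — is the workhorse outcome
endpoint in neuro-oncology, but it is rarely present in glioblastoma (GBM)
datasets because the clinical standard for assigning it (RANO criteria
applied by a multidisciplinary team over the whole chart) is subjective and
labor-intensive. `gliopfs` implements three automated, single-modality PFS
derivations that mine the electronic health record directly, plus the
statistical machinery to compare them against a clinical-standard date:

1. **Prescriptions.** Dexamethasone is the steroid of choice for managing
   progression symptoms in GBM, prescribed on a tapering schedule. All
   dexamethasone orders (generic keyword plus an editable brand-synonym
   list, any dose, any route) dated at least one month after CRT end are
   collapsed into a single taper course running from the first largest-dose
   order to the last smallest-dose order; its start is the progression
   date. The one-month blackout removes the routine post-surgical and
   on-treatment courses.
2. **Radiology reports.** Post-treatment brain-MRI reports are analysed
   with a rule-based pipeline: prefix-stem matching of progression- and
   stability-related terms, ConText-style attribution of negated,
   historical, hypothetical, family and (custom) surgical modifiers within
   directional, sentence-bounded, terminator-cut scopes, and a
   re-categorisation step (negated/historical progression counts as
   stability; surgically modified progression is set aside as probable
   pseudoprogression). A document indicates progression when unmodified
   progression terms strictly outnumber stability terms (one-to-one
   weighting); the first such report dates progression.
3. **Tumor volumes.** Each post-CRT contrast-enhancing (CE) tumor volume is
   divided by the fixed post-surgery, pre-CRT baseline CE volume; the first
   scan with a relative change of at least 1.05 (a ≥ 5% increase, boundary
   inclusive) dates progression.

Each derivation returns an auditable evidence payload (the taper course,
the per-report term assessments, the full ratio series), because a key
motivation for rule-based methods in this setting is that a clinician can
trace every determination back to the source datum.

## Comparison protocol

`summary()` on a fitted `pfs_endpoints` object reproduces the comparison
protocol: per-method descriptive statistics (progression percentage over
the full cohort; mean/sd/median/range of PFS over progressed patients),
paired differences from the clinical standard (negative = automated date
earlier), the fraction of automated dates within ±2 months of the clinical
date, a Kruskal–Wallis omnibus test restricted to patients progressing
under all four methods, and pairwise Wilcoxon signed-rank tests with
Bonferroni correction (family size 6: three methods against the clinical
standard plus the three automated pairs; exposed as an argument).

The signed-rank statistic W is the rank sum of the less frequent sign after
discarding zero differences (the classic variant). For up to 12 non-zero
pairs the two-sided p-value is exact, by enumeration of all sign patterns
of the observed — possibly tied — ranks,
`p = P(min(W+, W−) ≤ observed)`; beyond that a normal approximation with
tie and continuity correction is used. The Kruskal–Wallis H (tie-corrected,
χ² reference on k − 1 df) is delegated to `stats::kruskal.test()`, with an
explicit `H = 0, p = 1` guard when every pooled observation is identical.
Ordinary least squares (`stats::lm()`) supplies the method-versus-clinical
trendlines and the treatment-year trend check.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| month length | 30.4375 days | mean Gregorian month; all day→month conversions |
| post-CRT blackout | ≥ 30.4375 days, inclusive | earliest steroid order considered progression-related |
| volumetric threshold | 1.05 | relative CE change called progression (inclusive) |
| agreement window | 2 months | tolerance against the clinical date |
| Bonferroni m | 6 | pairwise test family size |
| lexicon | `default_lexicon()` | editable YAML term/trigger sets |

Numerical conventions: dates are whole calendar days without time-of-day;
ratios are compared at full floating precision (no rounding before
thresholding); percentages are rounded to integers and months to one
decimal *for display only*.

## Design decisions

Several choices were genuinely open and are recorded here as the package's
own conventions.

* **PFS origin.** All methods measure PFS from the CRT end date, the origin
  under which post-treatment surveillance is defined; a
  diagnosis-anchored origin would only shift every method by the same
  per-patient constant and cancel in all paired comparisons.
* **Month convention.** No calendar-month arithmetic: a fixed 30.4375-day
  month reproduces the familiar 404 days → 13.3 months conversion and
  makes `months_between()` exactly antisymmetric.
* **Filter boundary.** "One month after CRT" is operationalised as
  `order_date ≥ crt_end + 30.4375` days, boundary inclusive.
* **Dose ties.** The taper window start/end are exhaustive min/max over
  tied records — the only reading consistent with "first date of the
  largest dose … last date of the smallest".
* **Lexicon.** The shipped term lists are a reconstruction from RANO
  response-assessment language and the term-frequency profile typical of
  brain-MRI surveillance reports ("enhancement", "increased", "tumor",
  "abnormal", "stable", …). Results depend on the lexicon; it is editable
  YAML precisely because report phrasing is institution-specific.
* **Modifier precedence.** Stacked modifiers resolve as
  `NEGATED > HISTORICAL > SURGICAL > HYPOTHETICAL/FAMILY`. Negated
  stability terms are dropped (recategorising them as progression would
  invert a rule nobody states); stability terms under historical or
  surgical context still count as stability; hypothetical/family-only
  mentions are dropped in both categories.
* **Tie rule.** On a progression/stability tie the surgical-context count
  joins the stability side — surgical-cavity change is the canonical
  pseudoprogression mimic — so ties, including all-zero documents, never
  call progression.
* **Volumetric degenerate baseline.** A zero baseline CE volume (complete
  resection) makes the ratio undefined; the patient is flagged *not
  evaluable* (`progressed = NA`), distinct from a non-progressor, rather
  than inventing an infinite-growth rule. The baseline window is bounded
  above by the CRT end date since the patient table does not carry a CRT
  start date; the generator never emits mid-CRT scans, so the same
  pre-treatment scan is selected under either bound.
* **Eligibility.** "Two brain MRI scans" is read as two scans after CRT
  end, in addition to the pre-CRT baseline the volumetric method needs. A
  patient with no clinical progression date is a non-progressor when
  follow-up is complete and excluded (`followup_complete = FALSE`)
  otherwise.

## The synthetic cohort generator

No EHR extract of this kind can be shipped, so `simulate_cohort()`
generates one with known ground truth; every downstream stage is tested
against it. What it emulates, and the defaults:

* **Clinical PFS** is lognormal (`meanlog = log 6.5`,
  `sdlog = sqrt(2 log(13.3/6.5)) ≈ 1.197`), giving median 6.5 and mean
  13.3 months — a heavy right tail with occasional very long-term
  survivors. Only the first two moments can be matched with a two-parameter
  lognormal; the implied sd (~23.7 months) is accepted as is. 91/92
  patients progress.
* **Modality timing.** The taper course starts a Normal(4.5, 8.3)-month
  lag *after* the clinical date. The lag is deliberately untruncated:
  clinically, steroids can precede the consensus progression date (the
  plausible range extends to −6 months), and truncating at a small
  negative bound would shift the realised mean far from the nominal 4.5
  and destroy parameter recovery. Report- and volume-visible onsets
  *precede* the clinical date by Normal(6.9, 19.2) and Normal(2.6, 5.8)
  month leads, truncated to `[0, PFS]` — radiographic change generally
  appears before the multidisciplinary consensus is reached.
* **Surveillance** visits every 2–4 months (uniform over whole days inside
  the bounds) from CRT end until 12 months past progression, with a
  36-month minimum and a 150-month study-window cap.
* **Reports** are template-built exclusively from the shipped lexicon plus
  neutral filler, so each document's gold label is exact by construction:
  stability templates mix stability stems, negated-progression phrases,
  historical and surgical-cavity sentences; progression templates place
  2–3 unmodified progression stems against at most one stability stem.
  Post-onset reports use progression templates with probability 0.8.
* **Volumes** follow `baseline × (1 + 0.35)^(months past onset)` — a CE
  doubling time near 2.3 months, an aggressive-GBM figure — under 1%
  multiplicative noise (small relative to the 5% threshold, as
  segmentation error should be). A 0.46 fraction of progressors is
  *volume-silent*: their ratios are clamped below 1.05 forever, matching
  the observation that only about half of progressing patients ever show a
  ≥ 5% CE increase.
* **Modality silence.** Beyond the volume-silent fraction, 0.36 of
  progressors have no progression-triggered steroid course and 0.20 have
  reports that never switch to progression phrasing, yielding standalone
  detection rates near 63%, 79% and 54% of the cohort.

What the generator does **not** model: realistic clinical prose (templates
are deliberately clean, so passing the gold-agreement test shows the
context rules are implemented correctly, *not* that the lexicon would
perform at any particular level on real reports), pseudoprogression
dynamics beyond surgical-context sentences, repeat steroid courses,
scan-quality dropout, or any imaging pixel data. Conclusions from the test
suite are therefore about the correctness of the rules, never about
real-world accuracy.

Two derived scenario configurations are part of the package's validation
design. The *parameter-recovery* scenario (200 progressing patients, no
steroid-missing fraction) floors true PFS at 24 months: the one-month
post-CRT filter censors taper courses that start before it, i.e. lags below
`1 − PFS` months, and with PFS far from that boundary the censoring is
negligible and the lag mean is identified; the recovered mean
steroid-minus-clinical difference then falls within two standard errors of
the configured 4.5. The *perfect-information* scenario
(`perfect_information_config()`) sets all lags/leads to zero, detection to
certainty, noise and silent fractions to zero, CE growth fast enough to
cross 5% within a day, floors PFS at 1.5 months (so the taper clears the
post-CRT blackout) and removes the study-window cap (complete follow-up):
under it every method must date every patient within one surveillance
interval (≤ 4 months) of the true date, which the test suite checks
exactly.

## Problem sizes

The shipped tests run the full pipeline on cohorts of 8–92 patients, the
sign-structure check on 400 patients, rank-test oracle equivalence on 200
random small inputs, gold-label agreement on 500+ generated reports, and
distributional calibration on 5,000–100,000 direct draws — sizes chosen so
each property is measured with comfortable statistical margin while the
whole suite stays quick to iterate on.

## Limitations

The lexicon is a reconstruction and will not transfer to another
institution's reporting style without editing; the document decision is a
bare term-frequency comparison with one-to-one weighting (alternative
weightings are out of scope by design); the volumetric rule compares only
CE tumor against a single fixed baseline (no scan-to-previous-scan logic,
no RANO bidimensional products); and the comparison protocol conditions on
progression being detected, so method summaries describe *detected*
progressors, not the cohort — availability bias is intrinsic to
single-modality endpoint mining, and is precisely what the comparative
statistics are for.
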