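---
title: "Screening for RTK-amplified gastric cancer: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for RTK-amplified gastric cancer: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragcscreen)
```

## The screening problem

Only about one advanced gastric cancer in ten carries an amplified receptor
tyrosine kinase gene (*EGFR*, *HER2* or *MET*), yet those are the tumors
eligible for RTK-targeted therapy. Confirming amplification requires in situ
hybridization, which is too expensive to run on every case; routine
immunohistochemistry is cheap but only a surrogate. `ragcscreen` encodes a
staged screen: call every marker from routine stains, place each tumor in a
surrogate molecular subgroup, and route cases to confirmation assays or
sequencing so that effort concentrates where amplification is likely.

## Marker models and their assumptions

**RTK IHC.** Staining is banded 0/1+/2+/3+ on surgical-specimen criteria:
any score above 0 requires at least 10% of tumor cells stained; faint or
partial-membranous staining is 1+; weak-to-moderate complete/basolateral
membranous staining is 2+; strong complete/basolateral staining is 3+
(`hofmann_score()`). Scores of 2+/3+ are "positive" and trigger SISH. The
same bands are applied to all three receptors; MET's partly cytoplasmic
staining is handled by recording the membranous component, which is the
band-defining feature.

**SISH amplification.** Per nucleus we observe discrete gene signals,
small/large signal clusters, and chromosome (centromere) signals. Clusters
stand for unresolvable stacks of copies and are counted as 6 (small) and 12
(large) effective signals — a deliberate coarse model of saturated staining.
The case-level statistic is the ratio of pooled effective gene signals to
pooled chromosome signals; `ratio > 2.0` (strict) is amplified. A nucleus
with no chromosome signal is not evaluable and is excluded from both sums.
Defaults: `ratio_threshold = 2.0`, `min_cells = 60` evaluable nuclei pooled
over the two tissue-microarray cores. Pooling before dividing is the default
because the per-case ratio is a ratio of totals, not a mean of per-core
ratios; since no combination rule for the two cores is canonical, a
configurable alternative (`pool_cores = FALSE`) calls each core separately
and declares the case amplified when any adequate core is. Likewise
`min_cells_per_core = TRUE` gives a strict per-core reading of the
60-nucleus requirement.

**MMR.** Deficiency is co-loss of MLH1/PMS2 or MSH2/MSH6. Loss of a single
protein of a pair is biologically discordant and was not observed in the
source cohort; the default calls it deficient with a `discordant_pair` flag
(screening favors sensitivity — a discordant case should not silently pass
as proficient), while `mmr_single_loss = "strict_pair"` preserves the
literal pair rule. A case with all four stains missing is imputed proficient
with `mmr_not_evaluated`.

**p53.** Mutant-pattern is complete loss of expression or strong nuclear
staining in more than 50% of tumor cells — strictly greater, so exactly 50%
is wild-pattern. The alternative 60% cutoff reported for ovarian cancer is
not used.

**EBER.** Positive only for diffuse strong nuclear staining in all tumor
cells. Missing stains are imputed negative with `eber_not_evaluated`. This
imputation (like the MMR one) is what lets a cohort in which EBER was
evaluable in fewer cases than the total still assign every case a subgroup;
the flags propagate into subgroup tables so imputed calls remain visible.

## The two classification systems and the triage tree

Both systems apply the same precedence: EBER-positive first, then
MMR-deficient, then the p53 split. The putative-molecular system ends
p53-wild → pGS, p53-mutant → pCIN. The histologic-molecular system refines
the tail with Lauren type: p53-mutant cases are I-pCIN regardless of
histotype; p53-wild cases are D-pGS if diffuse, I-pCIN if
intestinal/mixed. Two invariants follow and are property-tested: EBV and
MMR memberships are identical between systems, and pCIN ⊆ I-pCIN while
D-pGS ⊆ pGS.

The triage tree (`triage()`):

1. EBV-positive or MMR-deficient → immunotherapy candidate.
2. Otherwise the RTK IHC panel: HER2 3+ → HER2-targeted therapy (SISH
   optional, informative only); EGFR or MET 3+ → SISH required, targeted
   therapy only if that gene is amplified; any 2+ → SISH required, an
   amplified gene becomes the target.
3. No overexpression, or nothing amplified → target sequencing (NGS).

When a required SISH result is absent the case is reported `sish_pending`
(the honest state for a lab that has not yet run the assay);
`defer_pending_to_ngs = TRUE` sends such cases to sequencing instead. Where
several 2+ genes are amplified the target is the first in the fixed order
EGFR, HER2, MET — a tie-break that keeps triage deterministic. Whether
p53-wild diffuse (D-pGS) cases should enter the IHC panel at all is not
decidable from the published description; the default routes them through
it, because amplified cases do occur outside I-pCIN and a screen that never
inspects them could not find those, and `route_dpgs_to_ngs = TRUE` encodes
the alternative topology. Every case records its `>`-joined decision path.

## Statistics

Screening accuracy treats the named subgroup as the screen-positive set:
sensitivity `100·tp/(tp+fn)`, specificity `100·tn/(tn+fp)`. Association
tests use the uncorrected Pearson chi-square (matching the conventional
cross-table analysis; the Yates-corrected statistic is reported alongside
for 2×2 tables), switching to Fisher's exact test when any expected cell of
a 2×2 table is below 5 — the conventional rule, logged per table via the
`method` column since no switching rule is canonical. The two-sample t test
is pooled-variance by default (Welch optional) and accepts printed
summaries (mean, SD, n) directly. Percentages compared against printed
tables are rounded half-up to one decimal (`round_half_up()`); full
precision is kept internally.

Kaplan–Meier and log-rank are implemented from first principles and
cross-checked against an independent reference implementation to 1e-9 in
the test suite. Ties between events and censorings at the same time are
resolved events-first (censored subjects remain at risk at that instant),
the standard product-limit convention. The k-group log-rank uses the full
hypergeometric covariance with a pseudo-inverse on the reduced
(k−1)-dimensional contrast, so degenerate risk sets cannot produce a
spurious statistic. Subjects with zero follow-up are rejected rather than
guessed at. Cox modeling is a thin adapter over `survival::coxph()` and is
outside the validated screening surface.

## Synthetic cohorts: what they emulate and what they do not

`expand_count_spec()` is deterministic: a count table (e.g. a printed
subgroup-by-amplification cross-tab) expands into exactly those per-case
records, with raw readings chosen so the pipeline recomputes the input
counts exactly — amplified cases get 60 nuclei at pooled ratio 3.0,
IHC-positive non-amplified cases 60 nuclei at ratio 1.0. Published tables
are marginal summaries of one cohort whose joint distribution is not
recoverable, so each analysis uses the fixture expanded from its own
table: the classification spec for subgroup shares and screening accuracy
(whose putative and histologic cross-tabs *are* mutually consistent and
therefore expand from one joint spec), the marker-profile fixture — built
by independent per-variable permutations — for per-marker prevalences
only. Nothing about cross-marker joints in the marker-profile fixture is
meaningful, and no acceptance quantity reads one.

`simulate_cohort()` is the stochastic counterpart. Defaults are calibrated
to the printed marginals (subgroup prevalences 0.061/0.115/0.144/0.680,
IHC positivity 0.158/0.061/0.085, amplification-given-positive
0.312/0.803/0.306); ages are truncated normal (56.1 ± 12.5, bounded to
18–100); follow-up is exponential per subgroup with the favorable-prognosis
subgroups (EBV-positive, MMR-deficient) given monthly hazards of 0.010
(recurrence) and 0.008 (death) against 0.025/0.020 for D-pGS and
0.018/0.015 for I-pCIN, censored uniformly over 12–120 months — magnitudes
chosen once as typical for resected advanced gastric cancer follow-up. The
SISH signal model draws chromosome signals as `1 + Poisson(1)` and gene
signals as Poisson with mean `true ratio × chromosome signals`; amplified
nuclei may condense signal mass into clusters without changing effective
totals. With 70 nuclei the pooled ratio has a standard error of roughly
0.09–0.13, so true ratios of 1.0 and 3.0 are separated from the 2.0
threshold by many standard errors — the caller-recovery property the test
suite measures. Markers are drawn independently of subgroup given the
prevalences, so the simulator does not emulate the real cohort's
marker–subgroup correlations (e.g. RTK positivity enriched in I-pCIN);
passing parameter-recovery tests therefore demonstrates calibration and
pipeline correctness, not fidelity of joint structure to any real cohort.
All randomness flows from the single `seed`; the global RNG state is never
touched.

## Numerical and degenerate-input conventions

- Amplification threshold and the p53 50% cutoff are strict inequalities;
  ratio exactly 2.0 and staining of exactly 50% fall on the negative side.
- Validation is total: every input row yields a record or a structured
  error naming the case and field; empty fields are missing markers and are
  imputed (with flags) only at calling time, never at I/O time.
- `rfs_months > os_months` warns and flags rather than errors, since
  registry extracts can contain it.
- Zero-margin contingency tables, zero truth-positives, constant vectors
  for correlation, and single-subject t-test groups all raise typed errors
  instead of returning NaN.
- Test problem sizes: the parameter-recovery check uses a 10,000-case
  simulated cohort (binomial 3·SE bounds), caller recovery 1,000 seeded
  replicates at true ratios 2.5/1.2, the Fisher-vs-enumeration sweep all
  2×2 tables with total at most 40, and the cross-system invariants 100
  seeded cohorts of 50 cases — sizes at which the targeted binomial bounds
  are tight enough to detect real defects while the suite stays fast.

## Limitations

- The package scores readings, not slides: no image analysis, no probe
  chemistry, no intratumoral heterogeneity modeling across cores beyond the
  two-core pooling options.
- The printed-table fixtures cannot restore the original cohort's joint
  distribution; conclusions drawn from cross-marker joints in the
  marker-profile fixture would be artifacts.
- Survival comparisons of the real cohort are not reproducible without
  patient-level follow-up; the survival code is validated by oracle
  equivalence and by simulation size/power properties instead.
- Triage output labels ("candidate") are classification outputs, not
  clinical advice.
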