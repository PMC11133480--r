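---
title: "Methods: gating, EG12, mRANO and survival statistics in cxtrial"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, EG12, mRANO and survival statistics in cxtrial}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cxtrial)
```

cxtrial implements the computational chain of an early-phase glioblastoma
trial combining radiotherapy with a CXCL12-neutralizing L-RNA aptamer:
single-cell phenotype gating of multiplexed immunofluorescence (mIF) tables,
a composite CXCL12-positivity biomarker (EG12), a modified-RANO radiographic
response engine with survival-event derivation, and the surrounding summary
statistics. This vignette explains each model, its assumptions and tunable
parameters, the synthetic cohort the test suite runs on, and the numerical
and design choices that were genuinely open.

## Phenotype gating

The gating stage starts *after* nuclear segmentation: its input is one row
per segmented cell with a nuclear area (µm²) and, per marker, the
nucleus/cytoplasm completeness fraction in [0, 1] that image-analysis
platforms such as HALO report. Two validity filters run first: DAPI nucleus
completeness ≥ 0.15 and nuclear area within [12, 1000] µm². Positivity per
marker is then a simple threshold on the completeness fraction:

| marker | threshold | compartment |
|---|---|---|
| DAPI | 0.15 | nucleus |
| CXCL12 | 0.35 | nucleus + cytoplasm |
| CD68 | 0.20 | nucleus + cytoplasm |
| CD31 | 0.30 | nucleus + cytoplasm |
| Ki-67 | 0.30 | nucleus |
| α-SMA | 0.35 | nucleus + cytoplasm |
| GFAP | 0.30 | nucleus + cytoplasm |

All comparisons are **inclusive** (a value exactly at threshold is
positive, an area exactly at a window bound is kept). The convention is not
dictated by the thresholds themselves; we chose ≥ because it matches common
image-analysis practice and fixed it everywhere, including the 10 mm lesion
measurability bound and the −50 %/+25 % response thresholds below.

Phenotype gates are conjunctions of marker calls: endothelial = CD31⁺;
pericyte = α-SMA⁺ ∧ CD31⁻; macrophage/microglia = CD68⁺; glioma = GFAP⁺ ∧
CD68⁻ ∧ CD31⁻ ∧ α-SMA⁻. As written, the gates allow a cell to be both
endothelial and macrophage/microglia (CD31⁺ CD68⁺). We deliberately keep
dual membership — both counts increment — and report the overlap count in
the profile, because collapsing it would require an ordering the gate
definitions do not supply. Pericyte excludes endothelial and glioma excludes
the other three *by construction*, and the test suite asserts those
exclusivities on arbitrary inputs.

Frequencies: E12, P12, M12, G12 are the CXCL12⁺ percentages *within* each
phenotype; the total CXCL12⁺ percentage uses **all** filtered cells (gated
or not) as denominator, since nothing narrower is well defined. A phenotype
with zero members reports `NA`, not 0 — propagating a fabricated 0 into the
EG12 score would bias it. Ki-67⁺ is computed and reported but feeds no
downstream statistic.

## The EG12 composite biomarker

E12 and G12 (percent units throughout) are combined with equal weights after
median-centering within the cohort:

$$\mathrm{EG12}_i = \tfrac12\left[(E12_i - \mathrm{med}(E12)) +
(G12_i - \mathrm{med}(G12))\right].$$

The score is signed; adding a cohort-wide constant to either component
leaves it unchanged, and a common rescaling of both components rescales it
equivariantly (asserted for affine transforms only — a general monotone
transform does not commute with median-centering). Medians are taken
**within each cohort separately** (treated and comparison cohorts are
dichotomized independently, each into equal halves when scores are
distinct). The median split sends scores strictly above the median to
"high"; ties at the median go to "low", a deterministic rule we fixed since
nothing prescribes the tie direction.

Spearman correlation with PFS uses tie-corrected mid-ranks; the two-tailed
p-value comes from the t approximation $t = r_s\sqrt{(n-2)/(1-r_s^2)}$ on
$n-2$ df, the method behind the p-values most statistics packages print. An
exact permutation p (all $n!$ rank permutations) is available for $n \le 8$;
the suite checks the two agree to within 0.02 there. Only patients with an
*observed* PFS event enter the correlation: a censoring time is not a
progression time, so a 10-patient cohort with one new-therapy censoring
contributes $n = 9$.

## The mRANO response engine

Days are integers from the first treatment day (day 0); the baseline scan is
the earliest visit. Lesions measurable at baseline (both perpendicular
diameters ≥ 10 mm) are target lesions (TL); the rest are non-target (NTL);
lesions first seen later are new lesions. SPD is the sum over TLs of
$d_1 \cdot d_2$ (mm²), with absent lesions contributing 0.

Per scan, the rules run in this order: **PD** if SPD rose ≥ 25 % above the
nadir (the minimum of baseline and all *prior* on-treatment SPDs) or a new
measurable lesion appeared; **CR** if all TLs and NTLs are absent — unless a
new non-measurable lesion appeared, which constitutes progression exactly in
that complete-response situation; **PR** if SPD fell ≥ 50 % below baseline;
**SD** otherwise. PR/CR are referenced to baseline and PD to the nadir —
the standard mRANO convention; the thresholds alone do not fix the
reference, so we state it explicitly. Patients with no TLs are assessed on
the non-target SPD with the same PD/CR/SD rules but can not reach PR
(non-measurable disease). Multiplying every diameter by a constant changes
no classification (scale invariance, tested).

A preliminary PR or PD must be confirmed by the next scan at least 42 days
later maintaining the state (CR maintains a PR). The 42-day window reads
"the successive scan after 8 weeks" with real-world jitter: scans are
scheduled q8w (56 days) but slip. A histopathologically confirmed
pseudo-progression voids the PD call at the affected scan.

PFS/OS derivation follows the trial's event algebra. The PFS event day is
the earliest of: (1) the day of the first preliminary-PD scan that was
sequentially confirmed — note the event is dated at the *preliminary* scan,
so delaying the confirming scan never moves the event earlier; (2) a scan
day with simultaneous clinical progression, irrespective of that scan's own
outcome; (3) the death day if death precedes clinical or radiographic
progression; (4) the day of an unconfirmed preliminary PD when no later
scan showed SD/PR/CR and the patient stopped treatment for clinical
progression, had no further assessments, or died. When a new anticancer
therapy starts before any such progression day, PFS is censored at the
new-therapy day; otherwise at last contact. One genuinely ambiguous corner:
an unconfirmed PD whose only qualification arrives *after* a new therapy
begins. We resolve it by letting a qualified PD day at or before the
new-therapy day count as progression and censoring otherwise, which keeps
the rule order total; the whole algebra is checked exhaustively against an
independently coded rule-enumeration oracle over every preliminary-response
sequence of up to 6 scans crossed with death/new-therapy/stop-reason
configurations.

Best radiographic response (waterfall semantics) is the extreme percent
change of SPD versus baseline over all on-treatment scans, deliberately
independent of the nadir-based PD rule.

## Survival and safety statistics

Kaplan–Meier estimation, the log-rank test and Cox regression are delegated
to the `survival` package (`survfit`, `survdiff`, `coxph` with Efron ties —
the common default; no tie method is otherwise mandated). The KM median is
the first time the estimate drops to 0.5 or below; 6-month PFS is evaluated
at day 183 (365.25/2, rounded). Small-cohort Cox fits (n = 10) can hit
monotone likelihoods; these are surfaced as a `separation` flag rather than
switching estimators, since plain HR/CI is what such trials report.

The Mann–Whitney U test enumerates all $\binom{n+m}{n}$ group assignments
exactly for $n+m \le 12$ (two-tailed p = 2·min(lower, upper tail), capped at
1; ties handled by mid-ranks) and otherwise uses the tie-corrected normal
approximation with continuity correction — matching `wilcox.test` in that
regime, which the tests assert.

Adverse events are tabulated by CTCAE grade (1–5) and by relationship
category, with percentages of total events to one decimal, rounding **half
away from zero** (clinical-table style, not banker's rounding); percentages
are always recomputed from counts, never stored. The grade ≥ 2 subset and
its study-drug-related share are recomputed the same way — so a listing with
84 grade ≥ 2 events of which 4 are drug-related reports 4.8 %, the value the
counts imply.

Dose escalation implements the modified 3+3: 0/3 DLTs escalate (or declare
the recommended phase-II dose at the top 600 mg/week level), 1/3 expands to
six, ≥ 2 DLTs at a level stop escalation with the MTD one level below;
cohorts short of 3 (or of 6 mid-expansion) keep enrolling. The whole
decision table over 0–6 patients × 0–6 DLTs is compared against a
hand-enumerated oracle.

## The synthetic cohort generator

The generator exists so every stage above is testable without patient data.
What it emulates, and with which defaults:

* **Cell tables.** Types drawn from a mixture (endothelial 0.03, pericyte
  0.03, macrophage/microglia 0.20, glioma 0.36, other 0.38 — keeping
  endothelial cells an order of magnitude rarer than glioma cells, as in
  GBM tissue). Completeness fractions come from Beta distributions —
  Beta(10, 2.5) for a cell's own lineage markers, Beta(1, 20) otherwise —
  chosen because Beta keeps values in [0, 1] and these shapes pass each true
  type through its gate with ≥ 0.95 probability at the default thresholds
  (the suite measures per-class recall ≥ 0.9 at 10,000 cells). CXCL12
  positivity per type defaults to 0.45/0.30/0.15/0.05 (E > P > M > G), with
  per-patient logit-normal jitter (SD 0.5) creating the between-patient
  spread the biomarker needs.
* **Survival.** PFS is exponential with log-hazard
  $\log h_i = \log h_0 + \beta \cdot z_i$, where $z_i$ standardizes the
  patient's latent EG12 (mean of latent E and G rates) against a
  configuration-derived reference distribution, $h_0 = \ln 2 / 174$ per day
  and $\beta = -1.5$ per SD **in the aptamer arm only**; the SOC arm draws
  PFS independently of EG12. This is the simplest proportional-hazards
  construction under which Cox recovery is well-posed. OS = PFS plus an
  exponential post-progression increment (median 215 days), guaranteeing
  PFS ≤ OS. About one patient in ten is censored at a new-therapy day drawn
  before progression; follow-up is administratively capped at 730 days.
  Standardizing against the reference distribution (not the sample) makes a
  patient's outcome depend only on their own draws, so enlarging a cohort
  never perturbs existing patients; all randomness streams from the cohort
  seed through stable per-patient sub-seeds.
* **Lesion courses.** 1–3 lesions of 8–40 mm per patient follow a
  piecewise-exponential diameter course: shrinkage to a nadir at 60 % of the
  progression scan day, then regrowth calibrated to put SPD well above the
  +25 % bound at the first scheduled scan on or after the true PFS day, so
  the response engine re-detects the truth on the q8w grid. Measurement
  noise is multiplicative log-normal with 5 % SD — a modest reading error;
  no published error model exists for bidimensional measurements here.
  Explicit scripts (segment slopes, disappearance days) override the
  derived course for scripted test scenarios.
* **PK.** $C(t) = C_{ss}(1 - e^{-kt})$ with $k = \ln 2 / 1.75$ d⁻¹ (over
  90 % of steady state after one week) and $C_{ss}$ = 0.01 µM per mg of
  weekly dose — 2.0 µM at 200 mg, strictly dose-proportional, above the
  1.5 µM pharmacologic threshold at every dose level, with the mobilized
  CXCL12 series plateauing below the drug curve. Only qualitative anchors
  exist for these constants (threshold exceeded at all doses, steady state
  in about a week, dose-proportional accumulation), so the defaults are
  calibrated to those claims and fixed.

What the generator does **not** emulate: spatial structure or image-level
artifacts (staining gradients, segmentation errors correlate in space, not
i.i.d. across cells), non-proportional hazards, informative censoring,
inter-rater variability in lesion reading, and PK inter-patient
variability. Green tests therefore demonstrate that the *rules and
estimators* are implemented correctly and recover known structure — not
that real tissue or real trial data satisfy the generative assumptions.

## Numerical choices and degenerate inputs

* Threshold and boundary comparisons inclusive everywhere (≥, documented
  above); mixture fractions must sum to 1 within 1e-9.
* Empty phenotype ⇒ `NA` frequency; empty filtered table ⇒ error; a
  constant vector ⇒ Spearman error (undefined), not `NA`.
* All-censored KM ⇒ median flagged undefined. A group with zero events in
  the log-rank ⇒ warning, statistic still returned.
* Median-split ties ⇒ "low". Percent rounding half away from zero to one
  decimal.
* The report provenance hash is FNV-1a over the canonical JSON of the
  configuration — a fingerprint for reproducibility bookkeeping, not a
  cryptographic digest.

## Problem sizes

The test suite and acceptance script use cohorts of 10–60 patients, cell
tables of 5,000–10,000 cells, 1,000 null cohorts (n = 40) for log-rank
type-I-error calibration, 200 cohorts (n = 50) for hazard-ratio direction,
200 seeds for the correlation properties and 20 seeds at 10,000 cells for
frequency-ordering recovery; the response-engine oracle enumerates every
preliminary-response sequence over up to 6 scans. These sizes give stable
Monte-Carlo margins for the asserted bounds while keeping a full run in the
low minutes.

One statistical note: with 10 patients per cohort, the *mean absolute* null
Spearman correlation is about 0.27 (the expectation of $|r_s|$ for
independent rankings at $n = 10$), so null behaviour is asserted on the
signed mean across simulations, which does vanish under independence.

## Limitations

The engine consumes scalar per-visit lesion measurements and event dates —
it does not read images, compute perfusion maps, or reproduce reader
judgment. The EG12 dichotomization inherits the usual caveats of
median-split biomarkers (winner's-curse bias in small cohorts). The 3+3
module implements the decision rules only, not operating characteristics of
alternative designs. All defaults were fixed once against the study
conditions described above and are not tuned to any particular output.
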