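---
title: "Methods: PDX preclinical trial analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PDX preclinical trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdxtrial)
```

This vignette is the package's account of its methods: the response
model, the statistics it computes, the conventions it fixes where the
field leaves room, and what the bundled simulator does and does not
emulate.

## In vivo response quantification

A PDX trial in the one-animal-per-arm design produces, for every model ×
arm, a short caliper time series. Volumes use the hemi-ellipsoid
approximation `V = (length × width²)/2` (mm³). The response scale is
percent change from the day-0 baseline, `ΔV_t = 100 (V_t − V_0)/V_0`,
bounded below by −100 (complete regression).

Two summary metrics drive classification:

* **BestResponse** — the minimum ΔV over days `t ≥ 10`. The 10-day
  window excludes transient post-enrolment dips that do not reflect
  drug effect.
* **BestAvgResponse** — for each day `t ≥ 14`, the arithmetic mean of
  all ΔV values from day 0 through `t` inclusive; the metric is the
  minimum of those running means. Including the day-0 zero in every mean
  is a deliberate reading of "from t = 0 to t": it damps the metric
  slightly and uniformly, and makes the day-0 term harmless rather than
  ambiguous.

Both windows are arguments (`br_window`, `bar_window`) and the whole
series is truncated at a study horizon (default 28 days) before any
metric is computed, so late regrowth beyond the protocol window cannot
leak into the call.

mRECIST categories apply strict inequalities in order CR → PR → SD, with
PD as the remainder (thresholds in `mrecist_criteria()`, overridable).
Strictness matters at the boundaries: a BestResponse of exactly −95
is PR, not CR. The rules are monotone — improving either metric can only
move a call toward CR — and this is tested as a property.

Degenerate inputs are handled explicitly: calipers with width > length
are swapped with a warning (transcription slips, not errors); a zero
baseline is an error; series that never reach day 14 cannot be
classified and are dropped with a warning rather than imputed; missing
measurement days are skipped, never interpolated.

## Cohort-level statistics

The objective response rate is the percent of CR/PR calls. A model
tested with at least two agents is *chemosensitive* if ≥ 2 arms achieved
CR/PR, otherwise *chemoresistant*; with fewer than two tested agents the
model is unclassifiable (`NA`). Two is the weakest reading of
"evaluated with multiple agents" and is exposed as `min_tested`.

Doubling-free survival takes, per animal, the first measurement day on
which volume reaches at least twice baseline (inclusive crossing), with
censoring at the last observed day. Kaplan–Meier estimation and the
two-group log-rank (Mantel–Cox) test are implemented directly — the
estimator and the observed-minus-expected statistic are small, auditable
loops — and the test suite cross-checks both against the `survival`
package on random data. Log-rank p-values are two-sided from χ²(1); no
multiplicity correction is applied across treatment arms, since per-arm
tests are reported as such.

Patient–PDX concordance collapses both sides to a binary vocabulary
(CR/PR → sensitive, SD/PD → resistant; `sensitive`/`resistant` accepted
verbatim) and counts per PDX-model × drug combination; a patient treated
before engraftment whose annotation is `untested` for a drug contributes
nothing. Counting per model × drug (rather than per patient) is a
convention this package fixes and documents: one patient with two
sublines compared on the same drug yields two combinations.

The exposure–response correlation is Pearson's r between a model's
prior-drug count and its mean BestAvgResponse over arms actually tested;
untested cells are never imputed.

## Expression scoring

* **Centering.** `median_center_log2()` takes matrices to
  median-centered log2 per feature. Centering is idempotent; linear
  input must be strictly positive.
* **Outlier scores.** `(x − Q3)/IQR` per feature, outlier iff
  score > 1.5 (strict). Quartiles use linear interpolation of order
  statistics at `h = (n−1)p + 1` (R's type 7), stated because no
  universal convention exists and the flag is threshold-sensitive.
  Scoring is *leave-value-in*: x contributes to its own feature's
  quartiles. That choice is conservative (a large spike inflates Q3 and
  IQR, shrinking its own score) but symmetric and simple; with cohort
  sizes around 30 the attenuation is small, and the planted-spike tests
  quantify it. Features with zero IQR never yield calls.
* **Signature scores.** Sum of positive minus sum of negative regulatory
  components on centered values, per sample. Scores are linear in the
  matrix, and flipping a component's sign negates its contribution —
  both tested as properties. Missing components are dropped with a
  message; an RPPA sample failing a total-protein correction-factor QC
  should be excluded before scoring (the bundled clinical table's one
  such exclusion is annotated upstream of this package).
* **ssGSEA.** Features are ranked by decreasing expression, ties broken
  by stable feature order; in-set features accumulate weight
  `rank^α` (α = 0.25 by default, the common choice; α = 0 gives uniform
  weights), out-of-set features accumulate uniformly, and the score is
  the summed difference of the two cumulative distributions. Scores are
  deliberately **unnormalized** — they are comparable within one
  analysis, not across feature universes — and the test suite pins them
  to a brute-force cumulative-sum oracle on small universes, including
  the sign-symmetry of complementary sets at α = 0.
* **RNA–protein correlation.** Per-probe Pearson over shared samples,
  pairwise-complete, Benjamini–Hochberg adjusted across probes
  (`stats::p.adjust`; the step-up definition is verified against a
  hand-rolled oracle in tests).

## Cohort fidelity conventions

The bundled annotation table (37 PDX lines from 36 tumors) carries
status strings as annotated in clinical records; parsing is rule-driven:

* ER: any nonzero percent or `+` is positive (so a 10% ER PDX is ER+);
  a parenthetical primary-tumor annotation (`"- (primary +)"`) is
  ignored — the sampled lesion governs.
* HER2: `+` or a FISH ratio ≥ 2.0 (`"FISH 2.2"`) is amplified/positive.
* Denominators differ by statistic and are encoded explicitly:
  ER/HER2 concordance counts **per tumor** (a multi-subline tumor counts
  once and is concordant only if all sublines agree); subtype
  concordance counts **per PDX line**, restricted to pairs with an
  available patient label; composition fractions are over PDX lines.
  These are the only conventions consistent with reporting both
  per-tumor receptor agreement and per-line subtype switching.
* Percentages are reported to one decimal, round-half-up, matching
  clinical-table convention (`take_rate(36, 81)` = 44.4).

The count of models with clinically established ER/HER2/germline-BRCA
alterations depends on an inclusion rule for benign and
uncertain-significance germline variants; `build_actionability()` makes
that rule explicit (benign/VUS excluded) rather than claiming any
particular published fraction.

## Actionability matching

Rules are a plain TSV snapshot (`actionability_rules()`) naming gene,
alteration class, optional exact variant and an opaque evidence tier;
live knowledge-base queries are out of scope so results do not drift
with database versions. Hotspot membership is an explicit variant list,
not a statistical call. A gene matched by several sources (say,
amplified *and* outlier-high) keeps one matrix column per source — no
precedence is imposed. Matrix construction is idempotent (set
semantics), order-stable, and every present cell traces to a provenance
record; ablation of the input record removes the cell.

## The synthetic cohort generator

`simulate_pdx_cohort()` exists so that every downstream operation has a
testable input with known truth. Its growth model is the minimal form
that produces all four mRECIST classes and regression-then-regrowth
kinetics: a two-compartment exponential

\[ V(t) = V_0\,[f_r e^{g t} + (1 - f_r) e^{-k t}] \]

where the resistant fraction `f_r` grows at rate `g` and the sensitive
remainder dies at rate `k` under drug; untreated arms have `k = 0`,
`f_r = 1`. Measurement noise is multiplicative lognormal on volume
(mean 1, CV = `noise_cv`) — caliper error scales with tumor size — and
noisy volumes are split back into calipers at a fixed aspect ratio of 1.
Prior treatment links to resistance linearly: each prior drug line adds
`prior_drug_effect` to `f_r` (clipped to [0, 1]), the simplest monotone
mechanism for acquired cross-resistance.

Defaults describe a mid-size single-agent trial: 30 models; untreated
plus four chemotherapy arms; twice-weekly measurement over 28 days;
100 mm³ enrolment volume; growth rates 0.03–0.09/day (volume doubling in
roughly 8–23 days); kill rates 0.05–0.35/day; baseline resistant
fraction 0–0.6; noise CV 0.10 (0.05 in the parameter-recovery checks,
which probe classification rather than noise robustness); mean prior-drug
count 3 with effect 0.08 per drug. Expression matrices carry a
subtype-structured block (70/27/3% Basal/HER2E/LumB mix, matching a
triple-negative-skewed breast PDX library) and planted outlier spikes at
Q3 + 3·IQR of the pre-spike distribution (2.5·IQR in the sensitivity
checks, the hardest spike the outlier caller is expected to recover).

Randomness uses one root seed with per-model child seeds from a fixed
counter scheme, so cohorts are bit-reproducible and stable under adding
models. The intended mRECIST category in the truth table is computed by
running the noiseless trajectory through the same classification chain —
parameter recovery then measures only the effect of noise.

What the simulator does **not** emulate: pharmacokinetics or
dose–effect mappings (simulated "drugs" are abstract and are not
predictions for real agents), immune or stromal compartments, spatial
heterogeneity, inter-animal variation beyond measurement noise,
count-based RNA-seq error structure, or correlated mutation/expression
landscapes. Passing tests therefore demonstrate correctness of the
statistical machinery under a clean generative model, not fidelity of
any biological claim about real cohorts.

## Problem sizes and budgets

The test and validation suites use sizes chosen to make the checks
statistically meaningful while staying quick on a laptop: 1,000 random
ΔV series against the brute-force BestAvgResponse oracle; 200 simulated
models (1,000 arms) for category recovery (≥ 90% at noise CV 0.05);
30-sample matrices for spike recovery (≥ 95% sensitivity at 2.5·IQR
spikes, zero false positives on constant features); 13 replicate pairs
for reproducibility, mirroring a realistic replicate budget. The full
suite runs in under a minute.

## Known limitations

* mRECIST thresholds and windows follow the published PDX convention
  but are configurable, and analyses mixing conventions are not
  comparable.
* The log-rank implementation is the two-group statistic; stratified or
  trend tests are out of scope, as are Cox models.
* ssGSEA scores are unnormalized (see above).
* Outlier calling assumes roughly unimodal per-feature distributions;
  strongly bimodal features (e.g. amplified vs diploid) can make Q3/IQR
  a poor reference.
* The annotation parsers understand the status vocabulary of the
  bundled table; site-specific strings may need the `er_positive()` /
  `her2_positive()` rules extended.
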