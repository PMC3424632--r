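---
title: "Mining prognostic thresholds from ambulatory blood pressure cohorts"
author: "remedbp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining prognostic thresholds from ambulatory blood pressure cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remedbp)
```

## The model

`remedbp` learns a single conjunctive threshold rule

$$\textbf{If } x_1 \,\langle rel\rangle\, p_1 \text{ and } \dots \text{ and }
x_m \,\langle rel\rangle\, p_m \textbf{ then } 1 \textbf{ Else } 0$$

for a rare binary outcome (cardiovascular death during follow-up) from
continuous, *changeable* risk factors: BMI, serum cholesterol, 24-h heart
rate, and the systolic/diastolic time-weighted level (WBP) and Average Real
Variability (ARV) of a 24-h ambulatory recording. One condition per selected
attribute; relations are inclusive; $\langle rel\rangle$ is $\ge$ when the
attribute is positively associated with the outcome and $\le$ otherwise.
The design goal is *sensitivity on the minority class with interpretable
output*, not maximal accuracy: on a 1:9-imbalanced cohort the trivial
all-negative classifier already scores ~89% accuracy and 0% sensitivity.

### Assumptions

- One recording per subject, times strictly increasing, duration ≤ 26 h.
- The outcome is binary and both classes are present for every fit.
- Attributes enter the rule independently (a conjunction; no interactions).
- Missingness is limited to one attribute (cholesterol by default) and is
  unrelated to outcome given sex and age — the imputation model's premise.

## Indices

With readings $x_k$ at minutes $t_k$ and gaps $w_k = t_k - t_{k-1}$:

$$\mathrm{ARV} = \frac{\sum_k w_k\,|x_k - x_{k-1}|}{\sum_k w_k},\qquad
\mathrm{WBP} = \frac{\sum_k w_k\,(x_k + x_{k-1})/2}{\sum_k w_k}.$$

Weighting by elapsed time makes both indices invariant to shifting or
uniformly rescaling the clock, and insensitive to irregular sampling.
**Convention choice:** "weight readings by the interval between successive
measurements" is ambiguous for the level index, because $n$ readings have
only $n-1$ intervals. We adopt the trapezoidal form (each interval
contributes the midpoint of its two bounding readings) because it is the
standard time-weighted 24-h mean and treats the two readings of an interval
symmetrically; the asymmetric alternative (weight reading $k$ by its
preceding gap, dropping reading 1) is available via
`compute_wbp(..., convention = "right")`. Gaps left by discarded artifact
readings are bridged at their true elapsed time, with no cap: capping would
need a cap value no guideline supplies.

## Preprocessing

A reading is discarded when **either** channel is out of range (systolic
outside (70, 260) mmHg, diastolic outside (40, 150), strict bounds): both
values come from one cuff inflation, so an impossible value on one channel
taints the reading. Subjects with fewer than 40 surviving readings are
excluded (strict `<`). Missing cholesterol is imputed deterministically by
ordinary least squares on sex (0/1) and age over complete cases — no
stochastic residual, so pipelines are reproducible; observed values are
never modified. The QC report states the missing percentage under both the
all-cells and the single-column denominator, because cohort summaries are
routinely ambiguous about which is meant.

## Attribute screening

Each attribute is screened independently with
$\operatorname{logit} P(y=1) = b_0 + b_1 x$, fitted by IRLS (tolerance
1e-8, ≤100 iterations), and selected when the two-sided Wald test on $b_1$
gives $P < \alpha$ (default 0.01). Under (near-)separation the Wald
statistic collapses as $|b_1|$ grows — the Hauck–Donner effect — so when a
fit does not converge or any fitted probability is pinned within $10^{-7}$
of 0/1 the p-value falls back to the likelihood-ratio test and the
association is flagged (`test = "lrt"`). Zero-variance attributes are
skipped. The screening table is ordered by ascending p-value; that order is
also the order in which rule conditions are refined, making the whole fit
deterministic. Attributes that fail the screen can be forced into a rule
explicitly (`build_rule(..., force = )`), mirroring the clinical practice of
carrying well-known risk factors along — this is never automatic.

## Partition search

The threshold search is the one genuinely open design point, and the
package fixes a concrete, reproducible procedure:

1. **Start** at the attribute's mean over positive-class rows. From there,
   moving the threshold in one direction (down for $\ge$, up for $\le$) can
   only increase sensitivity.
2. **Candidates** are midpoints of consecutive distinct observed values —
   exclusionary, exhaustive, and tie-free on the data — plus the extreme
   value, so the "predict everything positive" end is reachable.
3. **Walk** candidate by candidate in the sensitivity-increasing direction,
   tracking the best overall accuracy seen (including the start). Stop at
   the first candidate whose accuracy falls `epsilon` (default 0.01, i.e.
   one percentage point) or more below that running best.
4. **Return** the accepted candidate with the best accuracy; ties prefer
   higher sensitivity, then the candidate nearest the start.

Why "epsilon below the running best" rather than a per-step bound: with
midpoint candidates, one step typically reclassifies a single row, so any
per-step rule accepts every step once $n > 1/\epsilon$ and the walk always
runs to the extreme (sensitivity 1, specificity ≈ 0). Bounding the drop
from the best accuracy seen keeps the sensitivity-first character — the
walk happily trades up to a point of accuracy for sensitivity — while
preventing unbounded drift; it reproduces the hand-worked example
(`refine_partition(1:6, c(0,0,0,1,1,1), ">=", start = 5)` → 3.5) and
recovers planted thresholds to ±0.5 mmHg at cohort scale (the acceptance
suite checks ≥90% of 20 seeded cohorts at n = 2000 with 5% label noise).

For a multi-condition rule, thresholds are first refined marginally, then a
greedy coordinate pass re-refines each against the **conjunction**'s
confusion matrix — rows failing the other conditions are fixed negatives —
restarting each walk from the positive-class mean, and passes repeat until
no threshold changes (cap 25). Loosening any one condition only grows the
predicted-positive set, so the joint pass never lowers the conjunction's
sensitivity below its entry value. Thresholds print rounded to one decimal
but classify unrounded. Identical inputs give bit-identical rules: there is
no randomness anywhere in the fit.

## Evaluation

`stratified_kfold()` shuffles under a mandatory seed and deals rows to
folds class by class in one continuous round-robin, so per-fold positive
counts and per-fold sizes each differ by at most one — every fold keeps the
cohort's imbalance. `cross_validate()` fits on $k-1$ folds, scores the
held-out fold, and **pools the held-out confusion matrices by summation**;
pooled totals then equal the full cohort's class counts, and the pooled
matrix reads like a single cohort-level confusion matrix (averaging
per-fold percentages would instead weight folds equally regardless of
their positive counts). Sensitivity, specificity, and accuracy are reported
as percentages rounded to one decimal. The Gaussian naive Bayes baseline is
implemented directly (class-conditional independent normals, training-fold
priors, maximum posterior; per-class variances floored at 1e-9 with a
warning) and reuses the identical fold plan, so rule-vs-baseline
comparisons are paired.

## The synthetic cohort: what it emulates, and what it does not

The generator states one world and keeps it: 551 subjects, true prevalence
61/551 (~1:9), ~65 readings per 24-h recording, outcome planted by
`sbp_arv >= 9.6 and sbp_wbp >= 137`, labels flipped with probability 0.05.
Subject marginals follow the published shape of such cohorts: age
67.1 ± 8 y, 32.1% male, BMI 27.1 ± 5.6 kg/m², cholesterol 5.5 ± 1.3 mmol/L,
systolic WBP 133.8 ± 16.6 mmHg, heart rate 73.7 ± 9.8 bpm; the systolic ARV
marginal (9.8 ± 3 mmHg) is a typical 24-h value from the ambulatory
monitoring literature, since cohort tables rarely print it. Covariates are
drawn independently of outcome — a built-in negative control the screen
must reject. Positives satisfy every planted condition, negatives fail at
least one; `rule_margin` (default 0) can open a corridor around the
thresholds to make a noiseless cohort strictly separable, which the exact
cross-validation tests use (at margin 0 a held-out point can fall inside
the training gap at the boundary, so exact 100%/100% is not guaranteed).

Within-subject dynamics are AR(1) at the reading step with lag-1
autocorrelation `ar_phi` (default 0.5 at the ~22-min default sampling): ARV
measures successive differences, so white noise would collapse it to a
fixed multiple of the within-subject SD and make variability uninformative.
The innovation scale is set in closed form so the expected ARV of the
realized series equals the subject's target:
$\sigma^2_{stat} = \pi A^2 / (4(1-\varphi))$, from
$E|d| = \sqrt{2/\pi}\,\mathrm{sd}(d)$ and
$\mathrm{Var}(d) = 2\sigma^2(1-\varphi)$. Reading times sit on a jittered
grid spread over 24 h (so every recording passes the duration invariant);
per-subject RNG substreams are derived by hashing subject ids, making
cohorts reproducible under reordering.

**Not emulated:** circadian (day/night) BP structure, treatment effects,
outcome-correlated covariates, informative missingness, device-specific
error models. A green test therefore establishes that the pipeline recovers
what it planted under these stated conditions — not that the method would
find the same thresholds in a real cohort.

### Measurement blur, and what "low-noise" means

The ARV target pins the within-subject scale: a subject with ARV
9.6 mmHg at $\varphi = 0.5$ has $\sigma_{stat} \approx 12$ mmHg, so a
65-reading WBP estimate carries ~2.5–3 mmHg of error and ARV ~1 mmHg. That
blur is not just variance: negatives pile up against the planted boundary
(they must fail a condition), so blurring shifts the accuracy optimum *in
realized-feature space* upward — a grid search at 5-min sampling places it
about +1 mmHg above the planted WBP threshold. No search procedure can
recover ±0.5 mmHg from such features. The end-to-end integration test
therefore defines its low-noise configuration as: no label noise, 2-min
sampling (720 readings, research-grade), `ar_phi = 0.05`, n = 1500, and
requires the per-threshold *median* recovery error over seeds 1–3 (fixed
before first execution) to be ≤ 0.5 mmHg. Acceptance-scale recovery
(n = 2000, 5% label noise) instead uses the generator's noiseless true
feature values, isolating the rule-induction stage from measurement error.

## Numerical choices

- IRLS: epsilon 1e-8, maxit 100; Wald→LRT fallback as above.
- Partition walk: float comparisons carry a 1e-12 guard so "drops by
  exactly epsilon" rejects deterministically.
- Degenerate inputs: indices need ≥2 readings; screening needs both classes
  and nonzero variance; imputation needs ≥4 complete cases (warns < 10);
  an empty recording after filtering is legal (QC then excludes it).
- Rounding: metrics and printed thresholds to one decimal (`round`,
  banker's rounding); all internal arithmetic unrounded.
- Seeds: every stochastic entry point takes an explicit seed; library code
  restores the caller's RNG state.

## Known limitations

- The partition search is a documented stand-in for an algorithm whose
  original cut-point procedure is not fully published; other choices of
  accept rule would yield different (also defensible) thresholds on weakly
  separated data. `epsilon` and the exhaustive test oracle bound the
  behavior.
- Single rule, conjunctive only: no disjunctions, no per-subject
  probabilities, no multi-rule systems.
- Cross-validation evaluates the *procedure*; the reported all-data rule's
  own generalization error is not separately estimated.
- The naive Bayes baseline assumes class-conditional normality; it is a
  reference point, not a tuned competitor.
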