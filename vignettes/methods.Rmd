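---
title: "From frame-level detections to behavioral bouts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From frame-level detections to behavioral bouts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigbouts)
```

## The problem

Continuous video monitoring of group-housed weaned pigs, passed through an
object detector at 1 frame per second, yields a stream of per-frame,
per-class detections of agonistic behavior — aggression (head/body
knocking, chasing, mounting), ear biting and tail biting. Frame-level
detections are not the biologically meaningful unit: ethologists work with
*bouts*, temporally contiguous episodes of one behavior. `pigbouts`
implements the full post-detector chain — confidence filtering, per-second
presence rasterization, threshold-driven bout segmentation with temporal
hysteresis, daily and weekly pen-level metrics — together with the
surrounding measurement machinery: detector evaluation (IoU matching,
precision/recall/F1, AP and mAP50, confusion matrices), AI-versus-manual
agreement statistics (Pearson r, absolute-agreement ICC, Cohen's kappa
after bout alignment), growth and welfare arithmetic, and a seeded
synthetic generator so every stage is testable without video.

## Bout segmentation

A presence series is a binary vector at 1 Hz over one day (86,400 s):
`presence[t] = 1` iff at least one detection of the class with confidence
≥ 0.45 fell in second `t`. The segmentation rule has two thresholds:

* **onset**: a bout opens once the class has been present for a minimum
  number of *consecutive* seconds — 5 s for aggression, 3 s for ear and
  tail biting. Shorter isolated runs are discarded as incidental contact.
* **termination**: an open bout closes after the class has been absent for
  at least 5 s (all classes). Shorter absences are *bridged*: the bout
  continues through them.

Intervals are half-open `[start_s, end_s)` and the duration is
`end_s − start_s`, so a 5 s run has duration 5 and bridged-gap seconds
count toward the duration — the duration is the difference of the start
and end timestamps, not the count of present seconds. After onset, any
presence — even a single second — extends the bout until a qualifying
absence. Sub-threshold runs *preceding* the first qualifying run are not
part of the bout: the bout starts at the first second of the earliest run
meeting the onset minimum. Series are per-day; an episode spanning
midnight is truncated at the boundary, matching the per-day structure of
every downstream output. Classes are processed independently and may
overlap; no mutual-exclusivity constraint is imposed.

Two independent implementations ship: `find_bouts()`, a compiled
per-second hysteresis automaton, and `find_bouts_oracle()`, a base-R
run-length/block enumeration. The test suite asserts their equivalence
exhaustively on all binary vectors up to length 18 and on thousands of
random day-length vectors; with onset and gap both 1 the bouts reduce
exactly to the maximal presence runs.

## Daily and weekly metrics

`summarize_daily()` reports the three pipeline outputs per class and day:
bout count, total bout duration (s) and mean duration per bout (s); a day
with no bouts has a *missing* (not zero) mean duration. `weekly_means()`
averages the daily values over the available days of a week; the weekly
duration-per-bout is the mean of the daily means over days with at least
one bout, not a pooled per-bout mean — this matches the per-day output
structure of the pipeline. Days lost to camera gaps are excluded with a
warning, never imputed.

## Growth and welfare arithmetic

`compute_adg()` is weight gain over days (kg/d); `compute_fcr()` is
ADFI/ADG on an as-fed basis, with hay intake added to the enriched pens'
feed with no dry-matter correction, and a non-positive ADG flagged as
undefined rather than returned as an infinity. Ear lesions (0–3 per ear)
are averaged within pig (`ear_pig_score()`) and then within pen
(`pen_mean_score()`); tail lesions use a 0–4 scale and fecal scores 0–3,
with the pen mean as the experimental unit throughout. Note that weekly
FCR computed from *rounded* published group means need not reproduce
values originally computed on unrounded pig-level data; the package
computes the ratio from whatever inputs it is given.

## Detector evaluation

Matching is greedy and class-aware: predictions are visited in descending
confidence (ties broken stably by input order) and matched to the
unmatched same-class, same-image ground-truth box of highest IoU, subject
to IoU ≥ 0.5; each ground truth matches at most once. Average precision
integrates the precision–recall curve with all-point (continuous)
interpolation — the precision envelope `max(precision at recall ≥ r)` —
rather than a fixed-grid sample; toolkits differ in this choice and the
package's run/curve oracle in the tests defines the convention here.
TP/FP/FN counts (and hence P/R/F1) are taken at the deployed operating
threshold of 0.45, while AP sweeps all predictions. The confusion matrix
assigns predictions to ground truths per image by best IoU *regardless of
class*, so cross-class confusions land off-diagonal; unmatched boxes go to
a background row/column, and the normalized variant divides columns by
their sums.

## Agreement statistics

The paired unit is class × day. Event count, total duration and duration
per bout are compared with Pearson r and with the single-measure
absolute-agreement intraclass correlation ICC(A,1) (McGraw–Wong; the
"two-way random-effects, absolute agreement" convention), computed from
the two-way ANOVA mean squares with k = 2 raters:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

Unlike r, ICC(A,1) penalizes systematic offsets: if the AI halves every
duration, r stays 1 while ICC falls. When the two raters have equal means
and variances ICC(A,1) approaches r, but only asymptotically — the rater
term enters at order 1/n — so the tests assert convergence, not equality.
Cohen's kappa is chance-corrected categorical agreement; because no
defensible discretization of continuous counts/durations presents itself,
the package computes kappa only on the per-second binary presence labels
produced by `align_bouts()`, and reports it as a class-level statistic
alongside the per-metric r and ICC. Bout alignment also pairs events by
greatest temporal overlap (greedy, one-to-one, positive overlap required),
which supports event-level error analysis.

## The synthetic generator

The generator replaces the unavailable recordings with a stochastic model
whose defaults are the study conditions:

* **bout counts**: Poisson per class × day with rate
  `base × exp(trend × (day−1)) × group multiplier`. Control base rates
  (59.7 / 325.6 / 117.0 bouts per day for aggression, ear and tail biting)
  and mean durations (27.7 / 28.4 / 24.5 s) are calibrated to the week-1
  pen-level means of the study population; treatment multipliers
  (0.52 / 0.42 / 0.27) and day trends (−0.041 / −0.037 / −0.029 per day)
  reproduce the reported week-1→week-4 declines and enrichment effects.
* **durations**: rounded lognormal (σ = 0.5 log-s, a typical
  bout-duration skew) clipped to the class onset minimum, so every
  generated bout is in principle detectable.
* **placement**: uniform over the feasible configurations with same-class
  bouts separated by at least the 5 s termination gap. Rather than
  rejection sampling (which can loop arbitrarily long near saturation),
  starts are drawn by splitting the day's free time across the inter-bout
  slots with ordered uniform spacings — an exact uniform draw on the
  feasible set that terminates deterministically. A day whose *expected*
  bout time exceeds 86,400 s is refused.
* **detector noise**: independent per-second Bernoulli misses
  (default 5%) plus uniform false-positive seconds (default 5/day/class),
  with confidences Beta(5, 2) rescaled to [0.45, 1] so rendered detections
  survive the operating threshold; sub-threshold behavior is exercised by
  explicit low-confidence fixtures in the tests.
* **manual observer**: whole-bout misses (default 5%) and Gaussian
  boundary jitter (default SD 2 s, rounded to whole seconds).

Every generator output is a pure function of the master seed and the call
coordinates (group, day, class); substream seeds are derived
deterministically and the caller's RNG state is restored.

What the model deliberately omits: burstiness and occlusion-correlated
misses (real detectors fail in streaks when pigs pile up), inter-class
confusion in the detection stream, observer drift, and any spatial or
individual-identity structure. Passing tests therefore demonstrate that
the *pipeline arithmetic* is correct and that parameters are recoverable
under well-specified noise — not that the deployed detector achieves any
particular accuracy on real video, which is a property of the weights and
the footage, not of this package.

## Numerical and design choices

* Confidence boundary inclusive (≥ 0.45), matching common detector
  conventions; the filter is idempotent and monotone in the threshold.
* Duplicate detections in one second collapse to a single presence second;
  presence is invariant to record order and duplication.
* F1 is reported missing when precision or recall is undefined
  (zero denominators), and AP is undefined (with a warning) for a class
  with no ground truth, which is then excluded from mAP.
* Degenerate agreement inputs (constant series, zero variance) raise
  errors rather than propagating NaN; the one exception is kappa's
  perfect-agreement-on-one-category case, which is defined as 1.
* Problem sizes in the shipped tests and drivers: exhaustive oracle
  equivalence to vector length 18, 10³ random day-length vectors, 10⁴
  simulated days for rate recovery, 100 seeds for end-to-end recovery,
  28-day × 2-group experiment in the analysis scripts — sizes chosen so
  the stochastic checks have tight 3-SE bands while the whole suite stays
  comfortably fast on a laptop.

## Known limitations

Published agreement values (r ≈ 0.8–0.9 against human coders) and
detector metrics (mAP50 ≈ 0.95) depend on the original 24 h recordings
and trained weights, neither of which is distributable; the package
validates the measurement chain, not those numbers. Kappa on continuous
metrics is not reproduced (no discretization is stated for it anywhere);
the per-second kappa reported here is the defensible alternative. The
published tail-biting F1 (0.958) is inconsistent with 2PR/(P+R) on its
own printed precision and recall (0.955); the discrepancy is noted, not
resolved.
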