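---
title: "Frame-wise gaze divergence and group classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-wise gaze divergence and group classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of what it computes, which knobs
matter, and where its design was genuinely open. It states no empirical
number that the test suite or `scripts/acceptance.R` does not itself
compute.

## The statistic

The unit of analysis is the video frame. Gaze samples (60 Hz by default,
blinks coded missing) are averaged within half-open frame windows
`[f/fps, (f+1)/fps)` to give, per video, a frames × participants grid of
screen positions in pixels (origin top-left, y downward). For frame $f$
and group $g \in \{\text{low}, \text{high}\}$ with non-missing members
$i = 1..n_g$:

$$c_g(f) = \frac{1}{n_g}\sum_i (x_i, y_i), \qquad
  d_i(f) = \lVert (x_i, y_i) - c_{g(i)}(f) \rVert_2 .$$

Each participant's distance is to their **own** group's centre, so the
per-frame samples $\{d_i\}$ measure within-group dispersion; the two
groups' samples are compared with a two-sided pooled-variance Student's
t-test with $n_1 + n_2 - 2$ df. A video is summarised by the percentage of
evaluable frames with $p < \alpha$ (default 0.05, deliberately
uncorrected). The statistic is a *screening* device for locating
discriminative videos and frames; the package never interprets a single
frame's p-value inferentially, which is also why no multiple-testing
correction belongs here.

Assumptions worth keeping in view: distances within a group share an
estimated centre, so they are weakly dependent and right-skewed
(chi-like). The pooled t-test is therefore only approximately calibrated
per frame. The package's own null-cohort calibration (acceptance suite and
`scripts/acceptance.R`) measures the realised frame-level type-I rate at
the default study scale at roughly 5.2–5.4% rather than 5.0%: the skew and
the unequal group sizes (53/45) make the test mildly anti-conservative,
and blink-induced variation in how many samples make up a frame adds a
little more. This bias is a property of the method, not of the
implementation — it persists with blinks disabled — and is immaterial for
the statistic's screening role, where videos are compared against each
other on a common baseline. Users who need exact per-frame levels should
use a permutation reference, which is out of scope here.

### Degenerate frames and evaluability

* A frame is **evaluable** only if both groups have at least
  `min_per_group` (default 3) non-missing participants; other frames are
  excluded from the percentage denominator rather than imputed.
* Zero pooled variance with equal means (all participants of both groups
  glued to their centres symmetrically): $t = 0, p = 1$.
* Zero pooled variance with unequal means: treated as maximally
  significant ($p = 0$) and flagged `degenerate`.
* Distances to the *other* group's centre are computed and can be
  retained (`keep_distances = TRUE`) but never enter the test; the
  divergence reading — own-group dispersion — is the default because the
  test contrasts within-group spread, and the alternative contrast is left
  available to the analyst.
* The contributing participant is **included** in their own group's
  centre. Leave-one-out centres are available
  (`analysis_config(leave_one_out = TRUE)`); self-inclusion is the default
  because it is the plain reading of a shared group centre, at the cost of
  biasing distances slightly downward in small groups.

Frame windows are half-open and 0-indexed; the sample-to-frame map adds a
1 ns tolerance before flooring so samples sitting exactly on a window
boundary land in the correct frame despite binary floating-point rounding
of `t/fps`.

## Questionnaire scoring and grouping

GACS: 9 items, 7-point Likert, three subscales (anticipation, desire,
relief) of 3 items each. Subscale scores are item *sums* (not means), the
total is the sum of all nine (range 9–63); summing admits realistic
medians near the scale floor in low-craving samples. Published versions do
not pin a canonical item order for a data file, so the default
item-to-subscale map (items 1–3 anticipation, 4–6 desire, 7–9 relief) is
explicitly a package convention, overridable everywhere it is used.

Cronbach's α uses unbiased (n−1) variances throughout — the conventional
choice in scale reliability.

The median split labels a participant `high` iff total > median
(`ties_to = "low"`, the default; the alternative policy differs only on
participants scoring exactly the median). With discrete Likert totals,
ties at the median are common and the tie policy is what produces uneven
groups such as 53/45 from a 98-person cohort. Note a structural
consequence the generator tests made explicit: when the latent groups are
53/45, a tie-free median necessarily cuts 49/49, so ~4 low-group members
are mislabelled even under perfect score separation; tie clusters at the
median, sent to `low`, are what allow exact recovery.

## Video selection, features, and the leakage discipline

Videos are ranked by percent-significant-frames, descending, ties broken
lexicographically (determinism over elegance). The classifier input is the
minimal reading of "average viewing position": per selected video, each
participant's mean non-missing (x, y) — 2 features per video, default
`k_videos = 2` since the planted-signal design concentrates signal in two
videos. A fully missing (participant, video) cell is imputed with the
feature-column mean of the *training* participants and logged.

Every ranking carries a provenance token naming the participant subset it
was computed on. Inside the evaluation protocol, `select_top_k(...,
require_training = TRUE)` refuses a full-cohort ranking outright: using
test participants to choose videos is selection leakage. The package also
ships a deliberately leaky mode (`repeated_protocol(...,
demonstrate_leakage = TRUE)`) and a diagnostic feature set
(`signed_dispersion`: the mean of sign(t)·distance-to-pooled-centre over
the frames the selection analysis called significant) that makes the
point vividly — on *null* cohorts the proper pipeline stays at chance
while the leaky variant classifies held-out participants almost
perfectly, because chance-significant frames are a property of the full
sample realisation, test participants included. The demonstration is part
of the test suite.

Frame-level sub-selection (`frames_mode = "significant"`) restricts
features to frames significant in the training analysis; it is exploratory
and off by default.

## The evaluation protocol

Per repetition (default 18): a stratified 80/20 split
(floor-per-class quotas topped up by largest remainder, giving 78/20 at
n = 98); frame-wise statistics, ranking, selection, and imputation
statistics recomputed on the training side only; 5-fold stratified
cross-validation on training; plain accuracy on the held-out 20%.
Stratification is used because a 45/53 imbalance makes small unstratified
test sets noisy. Accuracy is the headline metric; per-repetition values
are retained so dispersion is always reportable.

"Default parameters" for the classifiers are pinned explicitly rather
than inherited silently from libraries (`classifier_defaults()`):
logistic regression (binomial GLM, threshold 0.5), k-NN (k = 5 on
training-standardised features), decision tree (rpart, cp = 0.01,
minsplit = 20), random forest (500 trees, mtry = floor(√p)). Pinning keeps
the protocol reproducible across library versions and ecosystems.

All randomness flows from one master seed. Stage r draws a child seed via
a Lehmer-mix (`derive_seed(master, r)`), so repetitions are independent
yet individually reproducible, and reports are byte-identical across
reruns with the same configuration.

## The synthetic cohort generator

`sim_config()` defaults emulate the target study design: 98 participants
(53 low / 45 high), 16 videos of 30 s in four advert categories (FUN,
SPORT, PRODUCT, CONTROL; four each), 60 Hz sampling on a 1280 × 900
display, 30 fps frames (a configurable convention — broadcast material
varies and the method is fps-agnostic), 5% i.i.d. blinks.

Gaze for participant i on frame f is
`target(f) + offset·1[high, signal frame] + N(0, σ²I)` with
σ = `sigma_base_px` (60 px) inflated to `dispersion_ratio`·σ (default 1.5)
for the high group on signal frames. `target(f)` is a reflected Gaussian
random walk (step SD 12 px/frame) shared by all participants — a minimal
moving point of interest. Signal frames are one contiguous block covering
`signal_frame_fraction` (default 0.5) of the video, starting a quarter of
the way in; default signal videos are the first two FUN videos. Values are
clamped to the screen, which truncates a small tail of the noise near
edges. GACS items are `1 + Binomial(6, p)` with `p` = 0.06 (low) / 0.28
(high): bounded in 1..7 by construction, giving cohort medians around
14–16 and median-split recovery of the latent groups of ~96–99% (capped
by the 53/45 structure discussed above). The 60-px noise scale and the
effect sizes are calibrated to make pipeline properties testable at desk
scale, not to mimic the original study's (unpublished) effect magnitudes.

What the generator deliberately does *not* emulate: saliency-driven or
content-driven gaze, fixation/saccade dynamics (the analysis consumes raw
samples by design), bursty blinks (an i.i.d. approximation; the pipeline
only consumes the missingness pattern), heavy-tailed gaze noise, and
participant-level idiosyncrasies such as calibration drift. Passing tests
therefore demonstrate that the *pipeline* behaves correctly under its own
statistical model — calibrated type-I behaviour, monotone power in the
planted effect, chance-level generalisation under the null, leakage
detection — not that any particular real cohort will show such effects.

## Problem sizes used in validation

The acceptance suite runs the full study scale: 10 null cohorts of
98 × 16 × 900 frames for calibration, 20 cohorts for planted-video
ranking, full 18-repetition protocols for the classification claims, and
1000+ random inputs for oracle-equivalence checks at 1e-10. Unit tests use
miniature cohorts (24 participants, 4 videos, 6 s at 20 fps) chosen so
each file runs in seconds; the properties they check are size-invariant.

## Known limitations

* Frame-level p-values are approximate (see calibration above); the
  percentage-significant summary inherits a slightly elevated baseline
  that cancels in comparisons across videos but should not be read as an
  exact 5% reference.
* The ANOVA over 16 video-level percentages treats videos as independent
  units; frames within a video are not independent, and the SEM bars carry
  the same caveat.
* Average viewing position is a deliberately minimal feature; cohorts
  whose groups differ only in dispersion (not location) are detectable by
  the frame-wise statistic yet nearly unclassifiable from position means —
  the generator's `offset_px` exists precisely to separate those two
  notions of signal.
* `min_per_group` protects against nearly-empty frames but heavy
  synchronized blinking (e.g. scene cuts) would silently shrink the
  evaluable denominator; the per-video `n_evaluable_frames` is always
  reported so this is visible.
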