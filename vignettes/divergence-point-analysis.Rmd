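---
title: "Divergence point analysis for visual world eye-tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Divergence point analysis for visual world eye-tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwpdpa)
```

## The problem

In the visual world paradigm (VWP), participants view an array of four
images while listening to a sentence such as *The tailor trims the suit*.
Because shifts of gaze closely track linguistic processing, the moment at
which looks to one image begin to exceed looks to another — the
**divergence point (DP)** — indexes when a listener has used the unfolding
sentence to distinguish the two. Anticipatory divergences (before the
target word is heard) are the behavioural signature of semantic
prediction. Comparing DP latencies across listener groups (for example,
older adults with normal hearing versus hearing loss, tested under
different listening demands) asks whether a group predicts *later*, which
is a different question from whether it predicts *at all*.

`vwpdpa` implements the full timecourse analysis: mapping raw gaze samples
to image regions of interest (ROIs), binning looks into fixation
proportions on a 20 ms grid aligned to a duration-normalized sentence
frame, filtering trials and participants, estimating each group's DP by
bootstrap, and contrasting groups through bootstrap confidence intervals.
A synthetic gaze generator with known ground-truth latencies makes every
stage testable without access to any real eye-tracking data.

## The sentence timeline and binning model

All items share one duration-normalized frame, "The [agent] [verb] the
[object]", so a single timeline gives the word onsets for every trial:

```{r}
tl <- default_timeline()
tl
```

Time zero is audio onset. The 2000 ms image preview that precedes the
audio is represented as negative time and excluded from the default
analysis window, which runs from 0 through the selection cue
(`audio_end + 2000` ms). Gaze is aggregated into half-open 20 ms bins
(`[start, start + 20)`); at a 1000 Hz sampling rate a complete bin holds
20 samples. Word onsets reported on the grid are rounded to the nearest
bin boundary with ties rounded up — a deterministic, documented
convention; the verb of the default frame lands at 700 ms and the object
at 1440 ms.

## From gaze samples to fixation proportions

An ROI is an image's 300 x 300 px box expanded by 50 px on every side, so
near-misses count as looks to the image. Containment is closed on all
edges; the default layout insets the four images so the padded boxes are
pairwise disjoint (a 1024 x 768 screen cannot hold two vertically stacked
400 px padded boxes centred on the quadrant centres, so the images sit
slightly towards the corners), which makes role assignment unambiguous.

A bin's value for a role is the *fraction of valid samples* assigned to
that role's ROI — not a binarized any-sample indicator — preserving
within-bin information at 1000 Hz. Invalid samples (blinks, track loss,
saccade gap markers) are removed from numerator and denominator alike; a
bin with no valid samples is *missing*, not zero, since zeroing blinks
would bias proportions downward. Trial-level bin proportions are then
averaged — unweighted, so each trial counts equally — into one timecourse
per participant x condition x role, and incorrectly answered trials are
dropped first (the analysis should reflect comprehension, not confusion).
The aggregation order (trial bins first, then across trials) is standard
VWP practice; the alternative (pooling samples across trials) would weight
trials by their valid-sample counts.

Trial accuracy is recomputed from the clicked image against the
condition's correct role, and any stored accuracy column is cross-checked
with mismatches reported. Participant-level filters (for example,
excluding intelligibility below 50%, or restricting to the 100%
intelligibility subset for sensitivity analyses) are arbitrary predicates
over the metadata columns, logged per criterion; regrouping (for example,
splitting by subjective effort at 15/100) uses mutually exclusive
predicates, and a participant matching none — such as a rating exactly at
a strict boundary — is dropped with a warning rather than silently
assigned.

## The divergence point estimator

For a contrast (two roles on an item subset), each 20 ms bin is tested
with a paired one-sample *t* test of the participant-level proportion
differences (`role_a - role_b`) against zero. The default tail is
one-sided (`role_a > role_b`) because every contrast of interest encodes a
directional hypothesis; two-sided testing is available by configuration.
The DP is the start of the first run of at least 10 consecutive
significant bins — a sustained 200 ms difference — which guards against
isolated spurious bins. Degenerate bins take the limiting verdict of the
*t* statistic: a constant positive difference is significant, a constant
zero or negative one is not; bins with fewer than two contributing
participants are never significant.

Uncertainty comes from a nonparametric bootstrap over participants:
`n_boot` (default 2000) resamples of the same size, drawn with replacement
within the group, with the bin tests and onset detection rerun per
resample. Participants are the resampling unit because they are the unit
of the *t* test; item-level resampling would address a different
inferential target. Resamples in which no qualifying run occurs are
**nonconvergent**: they are counted and excluded from the summary rather
than assigned a sentinel time (which would bias the mean), and a warning
is raised when they exceed 20%. The summary is the mean of the convergent
onsets plus a 2.5/97.5 percentile interval computed as order statistics
(`quantile type 1`), so CI endpoints always lie on the bin grid while the
mean may be fractional. The point estimate on the unresampled data
(`observed_dp_ms`) is reported alongside.

Group comparisons pair resample *b* of one group with resample *b* of the
other (the groups are bootstrapped independently; index pairing is an
arbitrary but valid coupling for differencing), drop pairs where either
side was nonconvergent, and summarise the difference distribution by its
mean and percentile CI. The categorical verdict follows the CI: strictly
containing zero means *not different*, a bound exactly at zero *marginal*,
zero outside *different*. Under full convergence the mean of paired
differences equals the difference of bootstrap means; both are reported.
Randomness is controlled by a single master seed from which each
(group, contrast) pair derives its own substream, so adding a group or
contrast never perturbs another's resamples.

## The synthetic cohort generator

The generator emulates the study design: three groups of roughly thirty
older adults; 24 predictable (CP) and 24 unpredictable (CU) items, 16
competition items whose two plausible images are disambiguated only at
the verb, and 40 neutral fillers; a 1000 Hz gaze stream over a 1024 x 768
screen with a 2000 ms preview and a selection cue 2000 ms after audio
offset.

Looking behaviour is generated per fixation, not per sample: fixation
durations are Gamma distributed (default mean 250 ms, shape 4), each
fixation's landing image is drawn from the condition's role probabilities
evaluated at the fixation's onset, and fixations are separated by 30 ms
saccade gaps recorded as invalid samples. Per-sample independence would
make consecutive bins nearly independent and the consecutive-bin criterion
effectively infallible; Gamma fixations reproduce the strong bin-to-bin
autocorrelation of real gaze, which is exactly the property that makes
this analysis hard (see Limitations).

Role probabilities use a pair-mass construction: the combined probability
of a designated image pair rises logistically from the uniform baseline
(2 x 0.25) to an asymptote (default 0.9), while the primary image's share
of that mass follows its own logistic transitions; the two remaining
images split the residual mass equally. Probabilities therefore sum to
one at every instant by construction. This one mechanism expresses all
five contrasts: CP items transfer mass to the target at the prediction
latency; CU items first favour the predicted-but-wrong image, then switch
the pair share to the actual target at the cost latency; competition items
raise the target+competitor pair early (stage 1) and split it late
(stage 2); neutral items rise only at a late lexical-access latency. The
default latencies mirror the qualitative result structure the generator
emulates — equal early latencies across groups and late-stage offsets of
+115/+190 ms for the hearing-loss groups — and are generator defaults, not
empirical claims. No published distributional description of the original
gaze data exists, so all generator defaults are explicit stand-ins.

The default logistic scale is deliberately sharp (`slope_ms = 10`): the DP
estimates the onset of a sustained difference, and with a shallow logistic
that onset precedes the midpoint by an amount that depends on power,
leaving "truth" ill-defined for recovery benchmarks. With a sharp rise the
nominal latency and the onset of detectable separation coincide to within
about one bin. Empirical VWP curves are shallower; this is a benchmarking
choice, stated as such.

What passing recovery tests on these cohorts shows: the full pipeline —
ROI assignment, binning, accuracy filtering, aggregation, testing, onset
detection, bootstrap — recovers a known latency and quantifies its
uncertainty correctly under realistic fixation autocorrelation. What it
does not show: robustness to features real data have and the generator
lacks (smooth pursuit and drift, systematic scan paths, off-ROI looks at
the screen centre, participant-specific image preferences, verb-driven
temporary looks to verb-related images).

## Numerical and design choices

* Half-open bins; a window is truncated to whole bins.
* Tie rule for grid rounding: half up.
* ROI containment closed on all edges; disjointness makes ties impossible.
* Zero-variance bins use the limiting *t* verdict (see above).
* Percentile CIs are order statistics, keeping endpoints bin-aligned.
* Nonconvergent resamples are excluded and counted, never imputed.
* Fixation-event input is expanded to the sample grid on read, so sample
  and event reports share one internal representation.
* Problem sizes in the test suite are scaled to what the properties need:
  recovery runs use one group of 30 participants and 24 items with 200
  bootstrap resamples, replicated across 50 cohorts for CI coverage.

## Known limitations

**Early-onset contamination of the bootstrap mean.** Real (and simulated)
gaze is autocorrelated over roughly a fixation duration, about 10-12 of
the 20 ms bins. The consecutive-bin criterion was designed to suppress
isolated false positives, but when the *t*-statistic series itself is
smooth over the criterion's own length, a resample whose participants
happen to share a small positive baseline drift can produce a sustained
spurious run long before the true divergence. A few percent of resamples
then carry onsets hundreds of milliseconds early, dragging the bootstrap
mean below the observed DP and stretching the lower CI bound — the effect
grows with the length of the pre-divergence baseline, so late contrasts
are affected most. Because the *t* test normalizes scale, no noise-level
setting removes this; only a stricter per-bin alpha, a longer run
criterion, or a restricted search window would. The observed
(unresampled) DP is far less affected, which is why it is always reported
alongside the bootstrap summary. Users comparing groups on long-baseline
contrasts should inspect the bootstrap distributions, not just their
means.

**Other limitations.** The generator does not simulate pupillometry,
audio, lexical competition dynamics, or verb-related transient looks;
saccade trajectories are instantaneous jumps; the accuracy model is a
per-condition Bernoulli without item or participant effects. Item-level
resampling is available as a research toggle in spirit but participant
resampling is the supported scheme. Growth-curve models, generalized
additive models and cluster-based permutation tests are out of scope.

## A minimal end-to-end run

```{r, eval = FALSE}
coh <- simulate_cohort(cohort_spec(seed = 1))
grid <- bin_grid(default_timeline())
series <- preprocess_cohort(coh$samples, coh$trials, grid = grid)
contrast <- contrast_spec("CP", "target", "cu_target", grid,
                          sub_experiment = "1", label = "prediction")
res <- dpa_by_group(series, coh$participants, contrast,
                    baseline = "PwNH", n_boot = 2000, seed = 1)
res$table
res$diff_table
```

The same analysis is available as a configured pipeline
(`run_pipeline()`, YAML via `run_config()`) that writes the accuracy
summary, filter log, DPA and group-difference tables, a verbatim config
echo, a JSON-lines stage log, and one timecourse figure per contrast with
word-onset lines and the DP marker with its CI whisker.
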