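---
title: "Extracting saccadic reaction times and estimating household-resource gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting saccadic reaction times and estimating household-resource gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazegrad)
```

`gazegrad` turns raw remote-eye-tracker gaze streams from infant saccade
tasks into per-trial saccadic reaction times (SRTs), quality and
reliability summaries, and mixed-model estimates of how those latencies
vary with an asset-based proxy of household resources. This vignette
explains the measurement model, the rules the pipeline applies, the
parameters that matter, what the synthetic-data generator does and does
not emulate, and the design decisions taken where the methodology left
room.

## The measurement model

A session consists of a sequence of square visual targets (about 5.7° of
visual angle on a side, 5.0° in the replication protocol) presented one at
a time at pseudo-random locations 9–14° apart, after an initial centre
target that is never analyzed (the gaze position at its onset is not
standardized). The SRT of a trial is the time from target onset to the
gaze's first entry into the target's area of interest (AOI). All internal
computation is in degrees of visual angle relative to the screen centre
(x rightward, y downward); pixel data are converted per axis by
`atan(offset_mm / viewing_distance_mm)`. At target eccentricities of at
most 14°, the flat-screen small-angle error of this per-axis conversion is
negligible against the AOI margin, so no oblique correction is applied.
The screen's pixel and physical dimensions are not part of any published
protocol constant and must be supplied as configuration.

AOIs are closed rectangles (boundary points count as inside — an arbitrary
but fixed convention) expanded on every side by a margin, 0.9° by default,
that absorbs calibration error in infant data. The margin applies equally
to the new target's AOI and to the previous target's AOI used by the
start-position rule, since both memberships face the same calibration
error.

## Preprocessing

Two preprocessing steps precede extraction.

*Binocular merging.* Each sample's two eyes are merged into one cyclopean
stream: the average when both eyes are valid, the single valid eye
otherwise, missing when neither is valid. The per-sample source flag
(`both_eyes`, `left_only`, `right_only`, `missing`) is retained and drives
a QC flag marking trials whose AOI-entry sample sits at a transition
between monocular and binocular tracking.

*Median filtering.* A 15-sample centred running median (125 ms at the
nominal 120 Hz) removes abrupt spikes. The filter is NA-aware: the median
is taken over the non-missing values in the window, the window shrinks at
the recording edges, and a missing sample stays missing. Gap preservation
is deliberate — the filter's purpose is spike removal, and the missing-run
validity criterion must see gaps, not interpolations. Any contiguous
artifact shorter than half the window embedded in locally stable gaze is
removed exactly; the 15-sample count (not the equivalent milliseconds,
which depend on the exact sampling rate) is the normative parameter. The
kernel is implemented in C++ for sample-level speed.

By default the eyes are merged first and the merged stream filtered, which
maximizes the number of non-missing samples available to the filter; a
`filter_first` option filters each eye before merging. The two orders are
exposed because the methodology fixes only the two operations, not their
order.

## Validity criteria and trial statuses

`validate_trial()` applies four criteria in a fixed order; the first
failure determines the status, so statuses are mutually exclusive and
rerunning validation is idempotent:

1. **Start position** (`reject_start_position`): the gaze must be inside
   the previous target's (margin-expanded) AOI at onset, and every
   non-missing sample between onset and AOI entry must remain inside it,
   except samples within the trailing 50 ms before entry (the saccade's
   transition period). The interval is read as starting at onset — the
   pre-onset gaze position is governed by the previous trial's own entry
   criterion — and the 50 ms exemption is a single trailing window, not a
   budget of off-target time spread across the interval; the alternative
   reading would admit trials whose gaze drifted off and back long before
   the saccade.
2. **Missing run** (`reject_gap_run`): no run of consecutive missing
   samples exceeding 100 ms between onset and entry. A run's duration is
   measured as last missing timestamp − first missing timestamp + one
   nominal sample period, a sample-count-free definition robust to
   timestamp jitter.
3. **Entry after missing** (`reject_entry_after_missing`): the entry
   sample must not be immediately preceded by a missing sample, otherwise
   the exact entry time is unknown.
4. **Response window** (`reject_window`): the SRT must lie in
   [100, 1000] ms; earlier entries are anticipatory, later ones are not
   responses to the target. Entries are scanned up to 1500 ms after onset
   so that late entries classify as window rejections rather than
   `no_entry`.

A trial with no detected entry is `no_entry`. Valid SRTs more than 2.5 SD
from the grand mean of log SRT are re-labelled `outlier` (two-sided,
single pass — no iteration to convergence, since the rule is defined once
over the dataset). The grand mean is taken within each visit's dataset by
default (`scope = "per_visit"`), because exclusion percentages are
reported per visit; a pooled option exists. On ideal log-normal data this
rule removes 2·(1−Φ(2.5)) ≈ 1.24% of trials, which the test suite verifies
by Monte Carlo. Participant-visits with at least 10 valid (non-outlier)
trials are retained. Whether exclusion precedes retention is not fixed by
the rule's statement; exclusion-first is implemented, so outliers never
count toward retention.

For social videos the same machinery extracts the latency from a spatial
cue (a pointing gesture or gaze shift) to the first look at the referred
object, inside 1-s post-cue windows. The start-position rule is replaced
by an at-onset constraint: the trial is rejected when the gaze is already
inside the target object's AOI at cue onset; otherwise the gaze may start
anywhere in the scene. The published phrasing of this criterion contains a
double negative that, read literally, would exclude exactly the trials the
latency construct needs; it is implemented as "must be outside the target
AOI at onset". Retention for the social task requires 3 valid latencies.

## Reliability and quality summaries

Within-session reliability is the odd–even split-half correlation: per
participant, valid trials are ordered by block and trial position and
split by odd/even position *among valid trials* (balancing half sizes
under missingness); the per-participant half-means are correlated across
participants, with a Fisher-z 95% CI. No Spearman–Brown correction is
applied by default, matching the convention of reporting raw half-length
correlations; the correction is available as an option. Under a
two-component model with between-child variance σb² and trial variance
σw², the expected split-half correlation at m trials per half is
σb²/(σb² + σw²/m); the tests and the acceptance study use this closed form
to calibrate generators and verify recovery (e.g. r = 0.78 at m = 12).

The retention summary mirrors the standard per-visit quality table:
participants assessed, participants retained, valid-trial counts, and the
mean valid-trial SRT. Because trials cluster within participants, the
trial-level mean's CI is computed by a seeded cluster bootstrap
(1000 resamples of participants); whether such tables are computed at the
trial or participant level is often ambiguous, so a participant-level mean
and CI are emitted alongside. Gaze-probability curves report, per AOI and
time point, the proportion of participants with non-missing gaze inside
the AOI among those with non-missing gaze, with Wilson binomial intervals,
plus an `elsewhere` series completing the partition.

## Covariates

The asset index is the first principal component of the standardized
binary asset indicators (correlation-matrix PCA, the Filmer–Pritchett
construction; no polychoric variant). Zero-variance indicators are
dropped; missing entries are mean-imputed with a 20% per-household
missingness cap. The component is oriented to correlate positively with
the raw asset count and standardized to mean 0, SD 1, so model
coefficients read "ms per SD of household resources" — the pivotal unit
convention, stated wherever coefficients are reported. The orientation
presumes the 1 = owns coding: a globally flipped coding yields the negated
index, because the wealth direction is not identifiable from the indicator
matrix alone. Screen time is constructed as the weekday/weekend average
(toddler protocol, responses on a 0–9 h grid) or as the weekly sum divided
by 7 (replication protocol; a 5/7–2/7 weighted variant is available in
case the sum was intended per-day). Age enters models as the deviation
from the visit's mean age.

## Gradient models

The primary model is a REML linear mixed model on retained valid trials:

```
SRT ~ Visit * Assets + Age_dev + Household_size + (1 | Participant) + (1 | Block:Trial)
```

Visit is categorical with the first visit as reference, so the assets main
effect is the gradient at the reference visit and the interactions are its
changes at later visits. `(1 | Block:Trial)` is read literally as a random
intercept for each block × trial-position combination — a
stimulus-sequence effect crossed with participants; a per-block-only
option is provided since the grouping could also be read as nested.
Wald 95% CIs are reported (the CI method is not fixed by the published
formula; Wald is the default of the lme4 ecosystem the formula syntax
implies). Singular fits are flagged, not hidden: a variance component on
the boundary is expected whenever the data carry no stimulus-sequence
effect. Covariate-adjusted fits add one fixed effect (screen time, HAZ).
Outcome-level fits (HAZ, milestone scores; one row per participant-visit)
drop the trial-level random effects and keep the participant intercept.

The replication-cohort variant is single-visit, adds the varying
previous-target distance as a fixed covariate, and uses family/child
nested random intercepts because some children share a household. When the
full random structure is singular or fails to converge, a fixed,
deterministic reduction sequence applies — first drop the trial-level
random effect, then the nested child effect — and the reduction used is
recorded on the fit object.

## The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated. Households draw a latent wealth factor; 29 binary indicators
(10 in the replication configuration) follow logistic item models on that
factor; household size is weakly positively associated with wealth,
matching the survey observation that assets are recorded per household.
Children inherit their household's asset index; each child-visit's latent
mean SRT is

```
visit_mean + beta_assets * index + beta_age * age_dev + beta_hsize * size_c + beta_haz * HAZ + child_intercept
```

with defaults taken from the observed cohort: visit mean SRTs
395/385/337 ms at mean ages 7.6/16.4/36.8 months, an asset gradient of
−5.43 ms/SD, −2.4 ms/month within-visit age slope, and a child-intercept
SD of 47 ms chosen so that the closed-form split-half reliability at 12
trials per half is near the observed 0.78. Trial latencies are drawn
log-normally around the latent mean (the outlier rule's log-scale
definition presumes right-skewed latencies); effects are additive in
milliseconds on the latent mean rather than on the log scale, so that the
linear mixed model is correctly specified and recovery studies have an
exactly interpretable truth. σ = 0.25 gives a trial-level CV matching the
within-session variability implied by the reliability table.

Raw sessions are rendered at 120 Hz: the gaze fixates the previous target
with 0.3° jitter, relocates instantaneously into the new AOI after the
drawn latency, and dwells 1000 ms before the next onset. Saccade flight
time is not modelled: at 120 Hz a 30–60 ms saccade spans at most seven
samples and the AOI margin dominates; programmed latencies are therefore
recovered to within one inter-sample interval (8.33 ms), which is the
granularity quoted for every oracle-equivalence check. Injected artifacts:
blinks (Poisson, log-normal durations with median 150 ms, so both harmless
sub-100 ms and rejecting super-100 ms gaps occur), isolated 1–7-sample
spikes (removed exactly by the median filter), monocular dropouts, and,
with 5% probability, pre-saccade wandering to a point 6° off the previous
target — far enough that even the diagonal of the expanded AOI rectangle
(half-extent 3.75°) cannot contain it — which must trigger a
start-position rejection. Inter-target scheduling is dwell-then-advance
(gaze-contingent scheduling is equally plausible; the choice is
configurable and does not affect any validity rule). Social videos place
the gaze on a speaker region and relocate it to the cued object after a
latency whose child-level mean is linear in the child's latent SRT
(slope 0.62 by default).

What the generator does **not** emulate: saccade kinematics and
undershoot/corrective saccades, smooth pursuit of moving AOIs, calibration
drift that varies over a session, head movement, or visit-to-visit changes
in data quality. Passing recovery tests therefore shows that the rules and
estimators are implemented correctly and are unbiased under the stated
conditions — not that real infant data meet those conditions.

## Numerical choices and degenerate inputs

Timestamps are kept as real milliseconds; nothing is resampled to a
uniform grid, because the gap criteria are defined on sample runs.
Recordings must have strictly increasing timestamps and a median
inter-sample interval within 20% of the nominal period. Degenerate inputs
fail loudly: all-constant asset indicators, constant outcomes (zero
residual variance), rank-deficient fixed designs (the aliased terms are
named), fewer than two valid trials in an outlier scope (warned no-op),
fewer than three paired participants for a cross-visit correlation. The
pixel↔degree conversion is verified as a bijection to 1e-9°. Pipeline runs
are deterministic given one seed; per-session seeds are drawn from the
base-seeded stream and stay within the 32-bit integer range.

## Problem sizes used in validation

The recovery studies are sized to be informative while remaining
desk-scale: gradient recovery uses replicate cohorts of 100 children × 3
visits × 20 programmed trials run through the full raw-gaze pipeline
(100–150 replicates); the reliability calibration uses 247 children × 24
valid trials (100 replicates); the visit-1 mean calibration uses 150
children; the outlier-rule tail uses 10^6 draws. On artifact-free
programmed-valid trial tables, recovery studies skip the 2.5-SD outlier
stage: symmetric log-trimming around the grand mean removes more
upper-tail trials from slower children and provably attenuates
between-child slopes (~7% under the default variance components), which
would bias a recovery estimand whose trials contain no artifacts to trim.
The rule's own behaviour is validated separately, analytically and by
Monte Carlo.

## Known limitations

The start-position rule's interval formalization and the 50 ms exemption
window admit alternative readings (documented above); the asset index's
scale matches published coefficients only up to the (unstated) scaling of
the original index; trial-level CIs in the quality table depend on the
bootstrap's clustering choice; and the monocular/binocular transition
audit is a QC flag, not an automated correction.
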