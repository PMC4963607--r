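---
title: "Methods: simulating and analysing Go/Nogo inhibitory-control training studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and analysing Go/Nogo inhibitory-control training studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nogosim)
```

# Overview

`nogosim` implements, end to end on synthetic data, the computational
workflow of a mobile inhibitory-control (IC) training intervention of the
kind used in randomized waitlist-control trials on eating behaviour:

1. an adaptive Go/Nogo/stop **training game engine** with simulated
   players and post-hoc log analysis;
2. an auditory Go/Nogo **assessment task** with counterbalancing and
   behavioural scoring;
3. an **ERP pipeline** from synthetic continuous EEG to reference-locked
   N2/P3 peak measures;
4. the **statistical toolkit** of such trials: one-way, mixed and
   repeated-measures ANOVA, partial eta squared, and dependent-means
   power analysis;
5. a **cohort simulator** for behavioural outcome tables.

Because no participant data ship with the package, every pipeline is
exercised against generators whose parameters are explicit and testable.
This vignette records the model assumptions, the tunable parameters and
their defaults, and the design choices made where the design was
genuinely open.

# The training game engine

Each game has 30 trials. The player must tap healthy-food images before a
reaction-time deadline (RTD) expires (Go), withhold to unhealthy images
(Nogo), and cancel an initiated response when an initially healthy image
switches to unhealthy after the timer starts (stop trials). The Go
proportion is redrawn uniformly from [0.70, 0.90] every game and realized
as an exact count, `round(p * 30)`, so per-game counts are integral and a
player cannot pre-prepare responses. Stop trials are carved out of the
non-Go allotment at `stop_trial_prop` (default 0.10 of that allotment);
their healthy-to-unhealthy change latency is uniform on 100–300 ms,
capped below the deadline. Neither the stop fraction nor the change
timing is constrained by published task descriptions, so both are
configuration fields.

**Difficulty staircase.** Published descriptions of such games state only
that difficulty increases "according to past performance", by shortening
the RTD and adding simultaneously displayed images (up to 12). We adopt
the simplest monotone rule: promote one level when a game's accuracy
(correct Go + correct inhibitions, over 30) reaches 85% **and** at least
one correct inhibition occurred; levels never decrease. The RTD schedule
is linear: 1000 ms at level 1, −50 ms per level, floored at 250 ms; the
image count equals the level, capped at 12. The maximum level defaults to
the point where both axes saturate.

**Adjudication** is a pure truth table. A Go response within the deadline
is `correct_go`; late or absent responses are omissions. Any response to
a Nogo stimulus is a commission. On stop trials, a response *before* the
change latency is a legitimate `correct_go` (the image was still
healthy); at or after it, a commission; withholding is a correct
inhibition. A grace window (default 150 ms) beyond the deadline registers
late taps without crediting them.

**Log analysis.** Participants below the adherence cutoff (default 90
games, 65% of the expected 140) are excluded. Each retained log is split
into `k = 3` consecutive session blocks whose sizes differ by at most
one, remainders going to the earliest blocks (120 games → 1–40, 41–80,
81–120; 91 games → 31/30/30), and game-level measures are averaged per
block to one data point per session.

# Simulated players

An agent is a small parametric response model: Go latencies are
truncated-normal (truncation at 100 ms and at deadline + grace,
inverse-CDF sampling so each trial consumes a fixed number of random
draws); Go stimuli are missed with probability `p_omission`; inhibition
fails with probability `p_commission`. On stop trials the agent always
prepares a response: if the sampled latency lands before the change it
taps (consistent with the adjudication table); otherwise it taps only
with `p_commission`. This is an engine-testing model, not a cognitive
claim — no evidence-accumulation fitting is attempted.

Learning is multiplicative per-game decay towards floors on **three**
channels: latency mean, commission probability, and omission probability.
The third channel deserves a note. Because the staircase promotes
whenever accuracy reaches 85% and never demotes, the deadline tracks the
player's current speed; the probability that a Go response beats the
deadline is therefore pinned near the promotion threshold for any agent
that only gets faster. With omission fixed, expected correct-Go counts
cannot rise across a course — yet practiced players of grid-tapping games
plainly stop missing targets. Decaying omission (novice mis-taps and
orientation failures fading with practice) is the mechanism that lets
correct-Go counts grow while the deadline tightens, which is the
qualitative signature such training data show: reaction times fall and
correct Go and Nogo counts rise across the three session blocks.

The `"learner"` preset starts at 430 ± 45 ms, 30% commission, 45%
omission, with decay rates 0.9926 (RT), 0.985 (commission and omission)
and floors of 190 ms, 3% and 2%. Under these defaults the early course is
dominated by omission learning at low levels, the mid-course by the
staircase climb, and the late course by a fast, accurate player at the
terminal deadline — producing monotone session trends in the published
direction in essentially all simulated cohorts (verified over seeded
replicates in the test suite). `"static"` (no learning) gives flat
session summaries *at fixed difficulty*; note that under an adaptive
deadline even a static player's observed mean correct-Go latency drifts,
because latencies are censored at a shrinking deadline.

# The assessment task

Two auditory Go/Nogo variants share 1100/2000 Hz tones (200 ms, 60 dB in
the original setting; tones are symbolic here) and differ in
interstimulus interval: 2500 ms ("longer RTD") versus 1250 ms ("shorter
RTD"), the shorter raising inhibitory demand. Sequences are exact-count:
every 100-trial sequence contains exactly 70 Go tones. Tone assignment
and task order are counterbalanced: the four cells cycle across the
roster within a session, and each participant receives the complementary
cell (both tone and order flipped) in the second session.

Scoring attributes each press to the most recent onset with a response
window equal to the ISI — the de facto deadline of the task. Published
task descriptions do not say whether presses during the 200 ms tone are
admissible; the full-ISI window is our convention. Ten practice trials
are generated but excluded from scoring and from the event markers
exported to the ERP pipeline.

# The ERP pipeline

**Synthesis.** Recordings contain the nine scalp sites F3, Fz, F4, C3,
Cz, C4, P3, Pz, P4 plus vertical/horizontal EOG, in microvolts, already
referenced (linked-ears referencing and amplifier gain are treated as
properties of acquisition, so synthetic data are generated post-hoc
equivalent). Each stimulus adds Gaussian-bump components on top of AR(1)
background noise: an N2 (frontal-maximal negativity, default −5 µV at Fz,
250 ms, 30 ms width) and a P3 (parietal-maximal positivity, default +8 µV
at Pz, 400 ms, 55 ms width), both scaled ×1.25 on Nogo trials. Blink
artifacts (default 160 µV on VEOG, 80% projection to frontal sites) are
inserted after a configurable fraction of events and are sized to exceed
the rejection threshold at scalp sites by construction.

**Quantification chain.**

* *Filtering*: zero-phase Butterworth low-pass via forward–backward
  application. Because the two passes square the magnitude response, the
  per-pass corner is placed above the nominal cutoff so the **overall**
  response is exactly 3 dB down at 24 Hz (a filter designed naively at
  24 Hz and run through `filtfilt` would be 6 dB down there). The
  second-order prototype keeps the passband below 12 Hz within 0.5 dB
  and attenuates 60 Hz below a 0.2 amplitude ratio.
* *Epoching*: −100 to +900 ms around each marker, converted to half-open
  sample intervals after rounding (500 samples at the 500 Hz default);
  the −100–0 ms channel mean is subtracted. Baseline subtraction is the
  field-standard reading of a prestimulus window and is applied by
  default.
* *Rejection*: an epoch is excluded iff any scalp-site sample lies
  strictly outside ±100 µV. EOG channels never trigger rejection.
  Rejection is monotone in the threshold, and accepted + rejected =
  total, both property-tested. Manual inspection of continuous data for
  muscle artifact is replaced by an optional high-variance segment mask
  (`high_variance_mask()`); the amplitude rule is implemented exactly.
* *Averaging*: point-wise means over accepted epochs, separately for
  correct Go and correct Nogo trials; grand means are unweighted across
  participants.
* *Peak measurement* is reference-locked: N2 latency is the largest
  negativity at Fz within 190–300 ms, P3 the largest positivity at Pz
  within 300–580 ms; amplitudes at all nine sites are read at exactly
  that latency. Ties resolve to the earliest sample; an extremum on the
  window edge is flagged (`boundary = TRUE`) since a monotone segment has
  no true peak. Because analyses of such data sometimes lock a frontally
  maximal P3 at Fz instead, the locking site and window are independent
  arguments rather than a hard-wired convention.

With ≥100 accepted epochs and noise SD at most 20% of a component's
amplitude, the pipeline recovers generating latencies within one sample
and amplitudes within 10% (and exactly, up to filter ripple, in the
noiseless limit) — verified in the acceptance tests.

# Statistics

All routines return the same tidy table: effect, F, df1, df2, p, partial
eta squared (`F·df1 / (F·df1 + df2)`), and a `degenerate` flag for
zero-error-variance cases (F reported as `Inf`, η² as 1; zero effect over
zero error is defined as F = 0).

* `oneway_anova()` / `oneway_from_summary()`: the classical
  between/within ratio. The raw-data path computes group summaries and
  shares the summary-path formulas, so the two agree to machine precision
  on unrounded summaries — and reconstruct a printed baseline table's F
  values from its rounded means/SDs to within rounding error. Two-group
  F equals the squared pooled t (property-tested against `t.test`).
* `mixed_anova()`: the 2 (time, within) × 2 (condition, between) design,
  from the cell-means decomposition. With two time points the within
  stratum reduces exactly to difference scores: the interaction F is the
  squared pooled two-sample t on `y2 − y1`, with df2 = N − 2 on
  complete cases; participants missing a time point are dropped with a
  message. The implementation is validated against `aov()` error strata
  to 1e−8.
* `simple_effects()`: time within each condition, the squared paired t
  with df (1, n − 1).
* `rm_anova_contrasts()`: one-way repeated measures over k sessions with
  uncorrected dfs (2, 2(n−1)) for k = 3 — matching complete-case
  reporting in the emulated literature — plus adjacent-session planned
  contrasts as paired comparisons with df (1, n−1). A Greenhouse–Geisser
  option exists and defaults off, mirroring the uncorrected convention.
* `factorial_anova()`: the general balanced mixed factorial (one between
  factor, any number of within factors) used for ERP peak amplitudes
  (condition × time × stimulus × RTD × laterality), built on `aov()`
  error strata and tidied to the package format.
  `laterality_contrast()` tests the paired left (F3, C3, P3) versus
  right (F4, C4, P4) difference.
* `required_n_dependent_t()`: smallest n whose noncentral-t power
  reaches the target; `power_dependent_t(n) = P(|T'| > t_crit)` with
  df = n − 1 and noncentrality d√n. For d = 0.5, two-tailed α = .05 and
  power .95 this yields n = 54, cross-validated by 10⁵-replicate Monte
  Carlo in the acceptance tests.

α is fixed at .05 throughout and no multiple-testing correction is
applied, mirroring the analysis style being emulated. Type-I calibration
of the interaction test is property-tested: on 2,000 null cohorts the
rejection rate at α = .05 stays within 5% ± 1%.

# The cohort simulator

`generate_cohort()` draws a balanced two-arm cohort in long format. Each
outcome is bivariate normal over the two time points at configurable
cell means/SDs with a test–retest correlation (default 0.6 — the
simplest model supporting the paired structure the mixed ANOVA assumes).
Demographics are truncated normal (age 19–61, mean 36.48, SD 14.22; BMI
> 25, mean 29.54, SD 4.05, respecting the inclusion criterion of the
emulated trial).

Default cells follow the published group means of the emulated study
where printed. Two caveats:

* The source's food-consumption table prints the training-arm healthy
  baseline as 63.17 and time 2 as 31.59 while its text describes an
  *increase* at time 2; the defaults follow the text (healthy
  31.59 → 63.17 kcal, unhealthy 234.68 → 76.50 kcal). Waitlist FCT and
  no-change cells are not printed and are filled with stable plausible
  values.
* Energy densities for the food-consumption test (nuts 6.07, grapes
  0.69, chips 5.36, candy 4.92 kcal/g) are configurable constants chosen
  from standard nutrition tables, not published study values.

`score_fct()` converts grams consumed to kcal and pools nuts + grapes
(healthy) versus chips + candy (unhealthy); it is linear in grams and
guards `0 ≤ consumed ≤ offered`. Instrument scoring
(`score_instrument()`) is keyed summation with reverse-keying support;
since the HEQ/TFEQ proprietary item keys are not public, the shipped
keys are editable placeholders (round-robin subgroup assignment, unit
weights) and subscale-level simulation is the default analysis path.

# What the generators do and do not emulate

The synthetic modules reproduce the *structure* the analysis code relies
on — learning trajectories interacting with an adaptive staircase, exact
trial composition, evoked components with plausible topography plus
blink-like artifacts, and paired outcomes with a time × condition
interaction. They do not emulate: genuine cognitive dynamics (no
evidence accumulation, no fatigue or time-of-day effects), realistic EEG
spectra beyond AR(1) shaping, non-blink artifact families (muscle,
drift, line noise), item-level psychometrics of the questionnaires, or
dropout mechanisms correlated with outcomes. Passing tests therefore
demonstrate correctness of the computational chain under controlled
conditions, not validity of any substantive claim about real
participants.

# Numerical conventions and problem sizes

* Time is in milliseconds everywhere; ms → sample conversion rounds to
  the nearest sample and epoch windows are half-open `[start, end)`.
* Channel order is fixed: the nine scalp sites, then VEOG, HEOG.
* All stochastic entry points accept `seed`; multi-participant drivers
  derive per-participant substreams so any one log is reproducible in
  isolation. Seeded runs are bit-reproducible.
* Degenerate ANOVA inputs are defined, not errors: F = 0 when both
  strata are empty of variance, `Inf` + flag when only the error stratum
  is.
* Test-suite problem sizes were chosen to keep the full suite around two
  minutes while leaving Monte-Carlo error well inside the asserted
  tolerances: e.g. 2,000 null cohorts for type-I calibration, 10⁵
  replicates for the power cross-validation, 120-event recordings for
  parameter recovery, and 20 seeded cohorts of 12 learners × 140 games
  for the session-trend direction property.

# Known limitations

* The mixed ANOVA targets the 2 × 2 design; higher factorials delegate
  to `aov()` via `factorial_anova()`, which uses Type-I sums of squares
  and assumes balanced within-factor structure.
* The staircase never demotes, as in the emulated game; agents stuck
  above their ability recover only through learning.
* The EEG writer stores continuous signal as plain CSV, which is
  convenient and portable but large for long recordings; no EDF/BDF
  binary export is provided.
* `run_study()` caps the number of participants run through the EEG
  stage by default (`erp_participants = 6` per arm) because EEG
  synthesis dominates run time; the statistical plumbing is unaffected.
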