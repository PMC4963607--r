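# nogosim

Simulation and analysis of Go/Nogo inhibitory-control training studies.

Randomized waitlist-control trials of mobile inhibitory-control (IC)
training combine four computational pieces: an adaptive Go/Nogo/stop
training game whose logs must be filtered, split into session blocks and
summarized; an auditory Go/Nogo assessment task; an ERP quantification
chain (low-pass filter → epoch → reject → average → reference-locked
N2/P3 peak measurement); and a battery of ANOVAs over behavioural
outcomes. `nogosim` implements all four as a headless, fully seeded R
package, together with the synthetic-data generators (simulated players,
evoked EEG, outcome cohorts) needed to exercise the whole workflow
without any participant data. It is aimed at methodologists who want to
prototype, power and validate such trials — and at anyone who needs a
well-tested reference implementation of the individual pieces.

## The statistics at the core

Every ANOVA routine returns a tidy table of *F*, (df₁, df₂), *p* and
partial eta squared,

  η²ₚ = F·df₁ / (F·df₁ + df₂),

Key routines:

* `oneway_anova()` and `oneway_from_summary()` — the classical
  between/within ratio, computable from raw data **or** from printed
  group means/SDs/ns (the two agree to machine precision on unrounded
  summaries);
* `mixed_anova()` — the 2 (time, within) × 2 (condition, between)
  design via the cell-means decomposition; the interaction *F* equals
  the squared pooled *t* on difference scores, with df₂ = N − 2;
* `simple_effects()` — time within each condition (squared paired *t*);
* `rm_anova_contrasts()` — one-way repeated measures over session
  blocks, dfs (k−1, (k−1)(n−1)), with adjacent planned contrasts;
* `required_n_dependent_t()` — smallest n whose noncentral-*t* power
  reaches a target for a dependent-means *t* test: with d = 0.5,
  two-tailed α = .05 and power .95 it returns **54**.

## Worked example

Simulate a 24-player training cohort, apply the 90-game adherence
cutoff, split each log into three session blocks and test the session
effect on reaction time:

```r
library(nogosim)

log  <- simulate_training(n_participants = 24, seed = 7)
kept <- filter_adherence(log, 90)          # 23 of 24 players retained
summ <- summarize_training(kept, 3)
aggregate(cbind(mean_rt_ms, mean_correct_go, mean_correct_nogo)
          ~ session, summ, mean)
#>   session mean_rt_ms mean_correct_go mean_correct_nogo
#> 1       1   363.8385        16.28263          4.709507
#> 2       2   248.8977        17.86504          5.285111
#> 3       3   187.1248        19.70644          5.544116
```

Reaction time falls while correct Go and Nogo counts rise — the
signature of a learning player under an adaptive staircase. The
repeated-measures ANOVA on the session means (here with 23 players,
hence dfs 2, 44) and a simulated outcome cohort analysed by the mixed
design:

```r
rm_anova_contrasts(summ, value = "mean_rt_ms")$main
#>    effect     F df1 df2         p partial_eta_sq degenerate
#> 1 session 51180   2  44 8.493e-75         0.9996      FALSE

cohort <- generate_cohort(cohort_spec(), seed = 7)   # 26 + 26 participants
mixed_anova(cohort, "heq_total")
#>           effect      F df1 df2         p partial_eta_sq degenerate
#> 1      condition  2.066   1  50 1.568e-01        0.03969      FALSE
#> 2           time  4.371   1  50 4.166e-02        0.08039      FALSE
#> 3 time:condition 27.749   1  50 2.931e-06        0.35690      FALSE
```

The healthy-eating score shows the generated time × condition
interaction (training arm improves, waitlist declines); `simple_effects()`
then splits it by arm. On the EEG side:

```r
sim <- simulate_assessment(assessment_spec("shorter"), "static", seed = 4)
rec <- lowpass_filter(synthesize_eeg(evoked_sim_spec(), sim$events, seed = 5))
ep  <- reject_epochs(extract_epochs(rec))       # ±100 µV rule, EOG exempt
erp <- average_erp(ep, "nogo")                  # correct Nogo trials
quantify_peak_locked(erp, "N2")[c("latency_ms", "reference_amplitude_uv")]
#> $latency_ms  [1] 248
#> $reference_amplitude_uv  [1] -6.4
```

A thin command-line interface over the same functions lives at
`inst/cli/nogosim` (subcommands `simulate-training`, `analyze-log`,
`simulate-assessment`, `simulate-eeg`, `erp-quantify`,
`simulate-cohort`, `rct-stats`, `power`, `run-study`).

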