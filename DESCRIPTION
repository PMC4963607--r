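Package: nogosim
Title: Simulation and Analysis of Go/Nogo Inhibitory-Control Training Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A headless engine for adaptive Go/Nogo/stop-signal training
    games with simulated players, an auditory Go/Nogo assessment task with
    counterbalancing and behavioural scoring, an event-related potential
    (ERP) pipeline (synthetic multichannel EEG, zero-phase low-pass
    filtering, epoching, amplitude-threshold artifact rejection, and
    reference-locked N2/P3 peak quantification), and the statistical
    toolkit used in randomized waitlist-control intervention trials:
    one-way ANOVA from raw data or printed summary statistics, mixed
    time-by-condition ANOVA with simple effects, repeated-measures ANOVA
    with planned contrasts, partial eta squared, and dependent-means
    power analysis.  Includes a cohort simulator for behavioural outcome
    tables so the full study workflow can be exercised end to end on
    synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
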