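# Independent oracles used across test files.

# Exhaustive truth table for trial adjudication, written directly from the
# task rules (no shared code with adjudicate()).
oracle_outcome <- function(kind, responded, rt, rtd, change) {
  if (!responded) {
    if (kind == "go") return("omission") else return("correct_inhibit")
  }
  if (kind == "go") {
    if (rt <= rtd) return("correct_go") else return("omission")
  }
  if (kind == "nogo") return("commission")
  # stop trial
  if (rt < change && rt <= rtd) return("correct_go")
  "commission"
}

# Amplitude ratio of a pure sinusoid through a filter, measured by
# regression on the quadrature pair (robust to phase).
sine_gain <- function(filter_fun, freq_hz, fs_hz, dur_s = 10) {
  t <- seq(0, dur_s, by = 1 / fs_hz)
  x <- sin(2 * pi * freq_hz * t)
  y <- filter_fun(x)
  # discard edges to avoid transients
  keep <- seq(round(length(t) * 0.2), round(length(t) * 0.8))
  c1 <- cos(2 * pi * freq_hz * t[keep])
  s1 <- sin(2 * pi * freq_hz * t[keep])
  fit <- lm(y[keep] ~ s1 + c1 - 1)
  sqrt(sum(coef(fit)^2))
}

# Build a minimal recording object around a signal matrix.
make_recording <- function(signal, fs_hz = 500, events = NULL) {
  colnames(signal) <- nogosim:::ALL_SITES[seq_len(ncol(signal))]
  rec <- list(signal = signal, fs_hz = fs_hz,
              channels = colnames(signal),
              events = events %||% data.frame(sample = integer(),
                                              label = character()),
              blink_events = integer(0))
  class(rec) <- "eeg_recording"
  rec
}

`%||%` <- function(a, b) if (is.null(a)) b else a
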