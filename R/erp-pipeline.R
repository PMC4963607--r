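#' Zero-phase low-pass filtering of continuous EEG
#'
#' Filters every channel with a Butterworth low-pass applied forward and
#' backward ([signal::filtfilt()]), giving zero phase distortion.  The
#' two passes square the magnitude response, so the per-pass corner is
#' placed above `cutoff_hz` such that the *overall* response is exactly
#' 3 dB down at `cutoff_hz` — matching an acquisition chain specified as
#' "down 3 dB at 24 Hz".  With the default second-order prototype the
#' overall magnitude rolls off with a fourth-order slope.
#'
#' @param rec An `eeg_recording`.
#' @param cutoff_hz Overall -3 dB point (default 24).
#' @param order Butterworth prototype order per pass (default 2).
#' @return The filtered `eeg_recording`.
#' @export
lowpass_filter <- function(rec, cutoff_hz = 24, order = 2) {
  if (cutoff_hz >= rec$fs_hz / 2) {
    stop("cutoff_hz must be below the Nyquist frequency")
  }
  # overall amplitude after filtfilt is 1/(1 + (f/fc)^(2n)); solve fc so
  # that the overall gain at cutoff_hz is 10^(-3/20)
  fc <- cutoff_hz / (10^(3 / 20) - 1)^(1 / (2 * order))
  if (fc >= rec$fs_hz / 2) stop("cutoff_hz too close to Nyquist")
  bf <- signal::butter(order, fc / (rec$fs_hz / 2), type = "low")
  rec$signal <- apply(rec$signal, 2, function(x) signal::filtfilt(bf, x))
  rec
}

#' Extract stimulus-locked, baseline-corrected epochs
#'
#' Cuts a window (default -100 to +900 ms) around every event and
#' subtracts each channel's mean over the baseline interval (default
#' -100..0 ms).  Windows are converted to half-open sample intervals
#' `[start, end)` after ms-to-sample rounding.  Events whose window falls
#' outside the recording are dropped with a warning.
#'
#' @param rec An `eeg_recording`.
#' @param window_ms Epoch window relative to stimulus onset.
#' @param baseline_ms Baseline interval; `NULL` skips baseline correction.
#' @return An `epoch_set`: list with `data` (epoch x channel x time
#'   array), `times_ms`, `channels`, `labels`, `correct` (if present on
#'   the events), `accepted` flags and `reject_reason`.
#' @export
extract_epochs <- function(rec, window_ms = c(-100, 900),
                           baseline_ms = c(-100, 0)) {
  fs <- rec$fs_hz
  s0 <- as.integer(round(window_ms[1] / 1000 * fs))
  s1 <- as.integer(round(window_ms[2] / 1000 * fs))
  n_t <- s1 - s0
  times_ms <- (s0 + seq_len(n_t) - 1L) / fs * 1000
  ok <- rec$events$sample + s0 >= 1 &
    rec$events$sample + s1 - 1L <= nrow(rec$signal)
  if (any(!ok)) {
    warning(sum(!ok), " event(s) too close to the record edge were dropped")
  }
  ev <- rec$events[ok, , drop = FALSE]
  n_ep <- nrow(ev)
  data <- array(NA_real_, c(n_ep, ncol(rec$signal), n_t),
                dimnames = list(NULL, rec$channels, NULL))
  for (e in seq_len(n_ep)) {
    idx <- ev$sample[e] + s0:(s1 - 1L)
    data[e, , ] <- t(rec$signal[idx, ])
  }
  if (!is.null(baseline_ms)) {
    bl <- times_ms >= baseline_ms[1] & times_ms < baseline_ms[2]
    if (!any(bl)) stop("baseline interval contains no samples")
    bl_mean <- apply(data[, , bl, drop = FALSE], c(1, 2), mean)
    data <- data - as.vector(bl_mean)  # recycles over the time dimension
  }
  es <- list(
    data = data, times_ms = times_ms, channels = rec$channels,
    fs_hz = fs, labels = ev$label,
    correct = if (!is.null(ev$correct)) ev$correct else rep(TRUE, n_ep),
    accepted = rep(TRUE, n_ep),
    reject_reason = rep(NA_character_, n_ep)
  )
  class(es) <- "epoch_set"
  es
}

#' Reject epochs exceeding an absolute amplitude threshold
#'
#' An epoch is rejected iff any sample at any scalp EEG site lies outside
#' `+/- threshold_uv` (default 100 uV).  The EOG channels are excluded
#' from the criterion: they carry the artifacts used to detect blinks but
#' are not "EEG sites".
#'
#' @param epochs An `epoch_set` (baseline-corrected).
#' @param threshold_uv Rejection threshold in uV.
#' @return The `epoch_set` with updated `accepted`/`reject_reason`.
#' @export
reject_epochs <- function(epochs, threshold_uv = 100) {
  scalp <- intersect(epochs$channels, SCALP_SITES)
  peak <- apply(abs(epochs$data[, scalp, , drop = FALSE]), 1, max)
  bad <- peak > threshold_uv
  epochs$accepted <- epochs$accepted & !bad
  epochs$reject_reason[bad] <- "amplitude"
  epochs
}

#' Average accepted epochs of one condition into an ERP
#'
#' Point-wise arithmetic mean over accepted epochs whose label matches
#' `condition` (and, by default, whose behavioural response was correct —
#' ERPs are computed separately for correct Go and correct Nogo trials).
#'
#' @param epochs An `epoch_set`.
#' @param condition Event label to average (`"go"` or `"nogo"`).
#' @param correct_only Restrict to behaviourally correct trials.
#' @return An `erp_waveform`: list with `data` (channel x time matrix),
#'   `times_ms`, `channels`, `condition` and `n_epochs`.
#' @export
average_erp <- function(epochs, condition, correct_only = TRUE) {
  keep <- epochs$accepted & epochs$labels == condition
  if (correct_only) keep <- keep & epochs$correct
  if (!any(keep)) {
    stop("no accepted epochs in condition '", condition, "'")
  }
  avg <- apply(epochs$data[keep, , , drop = FALSE], c(2, 3), mean)
  erp <- list(data = avg, times_ms = epochs$times_ms,
              channels = epochs$channels, condition = condition,
              n_epochs = sum(keep))
  class(erp) <- "erp_waveform"
  erp
}

# Component conventions: measurement window, reference site and polarity.
PEAK_DEFAULTS <- list(
  N2 = list(window_ms = c(190, 300), reference_site = "Fz", polarity = -1),
  P3 = list(window_ms = c(300, 580), reference_site = "Pz", polarity = +1)
)

#' Reference-locked peak measurement
#'
#' Finds the component's latency at its reference site — the largest
#' negativity at Fz in 190-300 ms for N2, the largest positivity at Pz in
#' 300-580 ms for P3 — and reads the amplitude at **all** nine scalp sites
#' at exactly that latency.  Ties take the earliest sample; a peak landing
#' on a window endpoint is flagged as a boundary peak (a monotone trace,
#' not a true extremum).
#'
#' The locking site and window can be overridden, e.g. to lock the P3
#' frontally when a dataset shows a frontal maximum.
#'
#' @param erp An `erp_waveform`.
#' @param component `"N2"` or `"P3"`.
#' @param window_ms,reference_site Optional overrides of the component
#'   conventions.
#' @return A `peak_measure`: list with `component`, `reference_site`,
#'   `window_ms`, `latency_ms`, `amplitudes_uv` (named, all scalp sites),
#'   `reference_amplitude_uv` and `boundary`.
#' @export
quantify_peak_locked <- function(erp, component = c("N2", "P3"),
                                 window_ms = NULL, reference_site = NULL) {
  component <- match.arg(component)
  conv <- PEAK_DEFAULTS[[component]]
  window_ms <- window_ms %||% conv$window_ms
  reference_site <- reference_site %||% conv$reference_site
  if (!reference_site %in% erp$channels) {
    stop("reference channel '", reference_site, "' not present")
  }
  in_win <- which(erp$times_ms >= window_ms[1] & erp$times_ms <= window_ms[2])
  if (!length(in_win)) stop("waveform does not cover the component window")
  ref <- erp$data[reference_site, in_win]
  # polarity -1: largest negativity (argmin); +1: largest positivity.
  pick <- if (conv$polarity < 0) which.min(ref) else which.max(ref)
  idx <- in_win[pick]
  scalp <- intersect(erp$channels, SCALP_SITES)
  out <- list(
    component = component,
    reference_site = reference_site,
    window_ms = window_ms,
    latency_ms = erp$times_ms[idx],
    amplitudes_uv = setNames(erp$data[scalp, idx], scalp),
    reference_amplitude_uv = unname(erp$data[reference_site, idx]),
    boundary = pick == 1L || pick == length(in_win)
  )
  class(out) <- "peak_measure"
  out
}

#' Grand mean across participant ERPs
#'
#' Unweighted point-wise mean of participant-level ERPs sharing the same
#' montage and time base.
#'
#' @param erps A list of `erp_waveform`s.
#' @return An `erp_waveform` whose `n_epochs` is the number of inputs.
#' @export
grand_mean <- function(erps) {
  stopifnot(length(erps) >= 1)
  ch <- erps[[1]]$channels
  tm <- erps[[1]]$times_ms
  for (e in erps) {
    if (!identical(e$channels, ch) || !isTRUE(all.equal(e$times_ms, tm))) {
      stop("site or time-base mismatch across ERPs")
    }
  }
  avg <- Reduce(`+`, lapply(erps, `[[`, "data")) / length(erps)
  gm <- list(data = avg, times_ms = tm, channels = ch,
             condition = erps[[1]]$condition, n_epochs = length(erps))
  class(gm) <- "erp_waveform"
  gm
}

#' Optional automated high-variance segment mask
#'
#' Flags samples belonging to windows whose pooled scalp-channel variance
#' exceeds `factor` times the median windowed variance — an automated
#' stand-in for manual marking of gross muscle-artifact sections in
#' continuous data.  Returns a logical mask (TRUE = clean); epoching can
#' proceed on the unmasked recording since the amplitude rule catches
#' affected epochs.
#'
#' @param rec An `eeg_recording`.
#' @param window_ms Mask window length.
#' @param factor Variance ratio above which a window is flagged.
#' @return Logical vector of length `nrow(rec$signal)`.
#' @export
high_variance_mask <- function(rec, window_ms = 500, factor = 10) {
  w <- max(1L, as.integer(round(window_ms / 1000 * rec$fs_hz)))
  scalp <- intersect(rec$channels, SCALP_SITES)
  n <- nrow(rec$signal)
  starts <- seq(1L, n, by = w)
  mask <- rep(TRUE, n)
  v <- vapply(starts, function(s) {
    idx <- s:min(n, s + w - 1L)
    mean(apply(rec$signal[idx, scalp, drop = FALSE], 2, stats::var))
  }, 1.0)
  bad <- v > factor * stats::median(v)
  for (i in which(bad)) {
    mask[starts[i]:min(n, starts[i] + w - 1L)] <- FALSE
  }
  mask
}
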