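#' Specification for synthetic evoked EEG
#'
#' Describes how to synthesize continuous multichannel EEG containing
#' stimulus-locked N2 and P3 deflections on top of spectrally shaped
#' background noise, with optional blink-like artifacts large enough to
#' trip the +/-100 uV epoch rejection rule.
#'
#' Each component is a Gaussian bump in time with a site-wise amplitude
#' topography: the N2 defaults to a frontally maximal negativity around
#' 250 ms, the P3 to a parietally maximal positivity around 400 ms
#' (slightly larger on Nogo than Go trials via `label_scale`).
#'
#' @param fs_hz Sampling rate (default 500 Hz).
#' @param components Named list of component definitions; each has
#'   `latency_ms`, `width_ms` (Gaussian SD) and `topography` (named uV
#'   amplitudes over the nine scalp sites).
#' @param label_scale Named multipliers applied to component amplitudes by
#'   event label (e.g. larger Nogo components).
#' @param noise_sd_uv Standard deviation of the background noise.
#' @param noise_ar AR(1) coefficient shaping the noise spectrum towards
#'   low frequencies (0 = white).
#' @param jitter_sd_ms Trial-to-trial latency jitter SD.
#' @param blink_rate Probability that an epoch-length window following an
#'   event contains a blink artifact.
#' @param blink_amplitude_uv Peak blink amplitude on VEOG; must exceed the
#'   rejection threshold at frontal scalp sites when injection is enabled.
#' @param blink_width_ms Gaussian SD of the blink waveform.
#' @return An object of class `evoked_sim_spec`.
#' @export
evoked_sim_spec <- function(fs_hz = 500,
                            components = list(
                              N2 = list(
                                latency_ms = 250, width_ms = 30,
                                topography = c(F3 = -3.5, Fz = -5, F4 = -3.5,
                                               C3 = -2, Cz = -3, C4 = -2,
                                               P3 = -1, Pz = -1.5, P4 = -1)),
                              P3 = list(
                                latency_ms = 400, width_ms = 55,
                                topography = c(F3 = 3, Fz = 4, F4 = 3,
                                               C3 = 5, Cz = 6, C4 = 5,
                                               P3 = 6.5, Pz = 8, P4 = 6.5))),
                            label_scale = c(go = 1, nogo = 1.25),
                            noise_sd_uv = 4, noise_ar = 0.9,
                            jitter_sd_ms = 0,
                            blink_rate = 0.05,
                            blink_amplitude_uv = 160,
                            blink_width_ms = 60) {
  for (cmp in components) {
    stopifnot(all(is.finite(cmp$topography)),
              all(names(cmp$topography) %in% SCALP_SITES))
  }
  stopifnot(fs_hz > 0, noise_sd_uv >= 0, noise_ar >= 0, noise_ar < 1,
            jitter_sd_ms >= 0, blink_rate >= 0, blink_rate <= 1)
  if (blink_rate > 0 && blink_amplitude_uv <= 100 / 0.8) {
    stop("blink_amplitude_uv must exceed the rejection threshold at ",
         "frontal sites (amplitude * 0.8 > 100 uV) when injection is on")
  }
  structure(
    list(fs_hz = fs_hz, components = components, label_scale = label_scale,
         noise_sd_uv = noise_sd_uv, noise_ar = noise_ar,
         jitter_sd_ms = jitter_sd_ms, blink_rate = blink_rate,
         blink_amplitude_uv = blink_amplitude_uv,
         blink_width_ms = blink_width_ms),
    class = "evoked_sim_spec"
  )
}

# Scalp projection of a blink: dominant on VEOG, strong frontally, fading
# towards parietal sites.  Fractions of the VEOG amplitude.
BLINK_TOPO <- c(F3 = 0.8, Fz = 0.8, F4 = 0.8, C3 = 0.3, Cz = 0.3, C4 = 0.3,
                P3 = 0.1, Pz = 0.1, P4 = 0.1, VEOG = 1, HEOG = 0.05)

#' Add a Gaussian bump to one channel column
#' @noRd
add_bump <- function(x, center_sample, sd_samples, amplitude) {
  half <- ceiling(4 * sd_samples)
  idx <- max(1, center_sample - half):min(length(x), center_sample + half)
  x[idx] <- x[idx] +
    amplitude * exp(-0.5 * ((idx - center_sample) / sd_samples)^2)
  x
}

#' Synthesize continuous EEG around a sequence of stimulus events
#'
#' Builds an 11-channel recording (F3, Fz, F4, C3, Cz, C4, P3, Pz, P4,
#' VEOG, HEOG) in microvolts: AR(1)-shaped background noise, plus, for
#' every event, each component's Gaussian bump scaled by its topography
#' and by the event label's multiplier, with optional latency jitter.
#' Blink artifacts are inserted after events at rate `blink_rate`, at a
#' random latency within 600 ms of the event onset.
#'
#' @param spec An [evoked_sim_spec()].
#' @param events A data.frame with `onset_ms` and `label` (e.g. a
#'   `trial_sequence` or the `events` element of
#'   [simulate_assessment()]); an optional `correct` column is carried
#'   through to the event markers.
#' @param seed Optional integer seed.
#' @param pad_ms Silence added before the first and after the last event.
#' @return An `eeg_recording`: list with `signal` (samples x channels
#'   matrix, uV), `fs_hz`, `channels`, and `events` (with `sample`
#'   indices); the indices of blink-contaminated events are stored in
#'   `blink_events`.
#' @export
synthesize_eeg <- function(spec = evoked_sim_spec(), events, seed = NULL,
                           pad_ms = 1000) {
  with_seed(seed, {
    fs <- spec$fs_hz
    ms2smp <- function(ms) as.integer(round(ms / 1000 * fs))
    onset_samples <- ms2smp(events$onset_ms) + ms2smp(pad_ms) + 1L
    n_samples <- max(onset_samples) + ms2smp(1000 + pad_ms)
    n_ch <- length(ALL_SITES)
    if (spec$noise_sd_uv > 0) {
      white <- matrix(rnorm(n_samples * n_ch), n_samples, n_ch)
      sig <- apply(white, 2, function(w) {
        x <- as.numeric(stats::filter(w, spec$noise_ar, "recursive"))
        x * spec$noise_sd_uv / sd(x)
      })
    } else {
      sig <- matrix(0, n_samples, n_ch)
    }
    colnames(sig) <- ALL_SITES
    for (e in seq_along(onset_samples)) {
      scale <- spec$label_scale[[events$label[e]]] %||% 1
      for (cmp in spec$components) {
        jit <- if (spec$jitter_sd_ms > 0) rnorm(1, 0, spec$jitter_sd_ms) else 0
        center <- onset_samples[e] + ms2smp(cmp$latency_ms + jit)
        sdsmp <- cmp$width_ms / 1000 * fs
        for (site in names(cmp$topography)) {
          sig[, site] <- add_bump(sig[, site], center, sdsmp,
                                  scale * cmp$topography[[site]])
        }
      }
    }
    blink_events <- integer(0)
    if (spec$blink_rate > 0) {
      hit <- runif(length(onset_samples)) < spec$blink_rate
      blink_events <- which(hit)
      for (e in blink_events) {
        center <- onset_samples[e] + ms2smp(runif(1, 50, 600))
        sdsmp <- spec$blink_width_ms / 1000 * fs
        for (site in names(BLINK_TOPO)) {
          sig[, site] <- add_bump(sig[, site], center, sdsmp,
                                  spec$blink_amplitude_uv * BLINK_TOPO[[site]])
        }
      }
    }
    ev <- data.frame(sample = onset_samples, label = events$label,
                     stringsAsFactors = FALSE)
    if (!is.null(events$correct)) ev$correct <- events$correct
    rec <- list(signal = sig, fs_hz = fs, channels = ALL_SITES, events = ev,
                blink_events = blink_events)
    class(rec) <- "eeg_recording"
    rec
  })
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz, %d events\n",
              ncol(x$signal), nrow(x$signal), x$fs_hz, nrow(x$events)))
  invisible(x)
}
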