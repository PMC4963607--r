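# Helper: noiseless recording with events and optional per-site bumps.
noiseless_spec <- function(...) {
  evoked_sim_spec(noise_sd_uv = 0, blink_rate = 0, jitter_sd_ms = 0, ...)
}

events_at <- function(onsets_ms, label = "nogo") {
  data.frame(onset_ms = onsets_ms, label = label)
}

test_that("the low-pass filter meets its magnitude response spec", {
  fs <- 500
  run <- function(x) {
    rec <- make_recording(matrix(x, ncol = 1), fs_hz = fs)
    lowpass_filter(rec, 24)$signal[, 1]
  }
  expect_equal(sine_gain(run, 5, fs), 1, tolerance = 0.05)    # passband
  expect_lt(abs(sine_gain(run, 12, fs) - 1), 0.056)           # < 0.5 dB
  g24 <- sine_gain(run, 24, fs)
  expect_equal(g24, 10^(-3 / 20), tolerance = 0.03)           # -3 dB point
  expect_lt(sine_gain(run, 60, fs), 0.2)                      # stopband
})

test_that("filtering rejects cutoffs at or above Nyquist", {
  rec <- make_recording(matrix(rnorm(1000), ncol = 1), fs_hz = 100)
  expect_error(lowpass_filter(rec, 50), "Nyquist")
})

test_that("epoch extraction windows, counts and baseline correction are exact", {
  fs <- 500
  n <- 6000
  sig <- matrix(7, n, 11)  # constant 7 uV everywhere
  rec <- make_recording(sig, fs,
                        events = data.frame(sample = c(1000, 2000, 3000),
                                            label = "go"))
  ep <- extract_epochs(rec)
  expect_equal(dim(ep$data), c(3, 11, 500))  # 1000 ms at 500 Hz, half-open
  expect_true(all(ep$data == 0))             # constant removed by baseline

  # a step of +4 uV at stimulus onset survives baseline correction exactly
  sig2 <- matrix(0, n, 11)
  sig2[2000:n, ] <- 4
  rec2 <- make_recording(sig2, fs,
                         events = data.frame(sample = 2000, label = "go"))
  ep2 <- extract_epochs(rec2)
  post <- ep2$times_ms >= 0
  expect_true(all(ep2$data[1, , post] == 4))
  expect_true(all(ep2$data[1, , !post] == 0))

  # events too close to the record edge are dropped with a warning
  rec3 <- make_recording(sig, fs,
                         events = data.frame(sample = c(10, 2000),
                                             label = "go"))
  expect_warning(ep3 <- extract_epochs(rec3), "dropped")
  expect_equal(dim(ep3$data)[1], 1)
})

test_that("amplitude rejection is exact at the threshold and ignores EOG", {
  fs <- 500
  sig <- matrix(0, 4000, 11)
  rec <- make_recording(sig, fs,
                        events = data.frame(sample = c(1000, 2000, 3000),
                                            label = "go"))
  ep <- extract_epochs(rec)
  # one sample at +101 uV on C3 in epoch 2 only
  ep$data[2, "C3", 250] <- 101
  # a huge excursion on VEOG in epoch 3 must not trigger rejection
  ep$data[3, "VEOG", 100] <- 400
  out <- reject_epochs(ep, 100)
  expect_equal(out$accepted, c(TRUE, FALSE, TRUE))
  expect_equal(out$reject_reason[2], "amplitude")

  # exactly +/-100 is not "outside +/-100"
  ep$data[2, "C3", 250] <- 100
  expect_true(all(reject_epochs(ep, 100)$accepted))
})

test_that("rejection is monotone in the threshold and conserves counts", {
  set.seed(31)
  spec <- evoked_sim_spec(noise_sd_uv = 30, blink_rate = 0)
  rec <- synthesize_eeg(spec, events_at(seq(0, 99) * 1250), seed = 32)
  ep <- extract_epochs(rec)
  rejected <- vapply(c(50, 80, 100, 150, 500), function(th)
    sum(!reject_epochs(ep, th)$accepted), 1L)
  expect_true(all(diff(rejected) <= 0))
  th <- 80
  out <- reject_epochs(ep, th)
  expect_equal(sum(out$accepted) + sum(!out$accepted), length(out$labels))
})

test_that("injected blinks reject exactly the contaminated epochs", {
  spec <- evoked_sim_spec(noise_sd_uv = 0.5, blink_rate = 0.3,
                          jitter_sd_ms = 0)
  rec <- synthesize_eeg(spec, events_at(seq(0, 59) * 1250), seed = 41)
  ep <- reject_epochs(extract_epochs(rec))
  expect_gt(length(rec$blink_events), 0)
  # blinks land within 600 ms of their event; allow spill into a neighbour
  expect_true(all(rec$blink_events %in% which(!ep$accepted) |
                    (rec$blink_events + 1) %in% which(!ep$accepted)))
  # every rejected epoch is adjacent to an injected blink
  for (r in which(!ep$accepted)) {
    expect_true(any(abs(rec$blink_events - r) <= 1))
  }
  # with blinks off, nothing is rejected at this noise level
  rec0 <- synthesize_eeg(noiseless_spec(), events_at(seq(0, 19) * 1250),
                         seed = 42)
  expect_true(all(reject_epochs(extract_epochs(rec0))$accepted))
})

test_that("condition averages equal the brute-force mean of accepted epochs", {
  set.seed(51)
  spec <- evoked_sim_spec(noise_sd_uv = 8, blink_rate = 0)
  labels <- rep(c("go", "nogo"), 25)
  rec <- synthesize_eeg(spec, events_at(seq(0, 49) * 1250, labels), seed = 52)
  ep <- reject_epochs(extract_epochs(rec))
  erp <- average_erp(ep, "go")
  keep <- ep$accepted & ep$labels == "go"
  expect_equal(erp$data,
               apply(ep$data[keep, , , drop = FALSE], c(2, 3), mean),
               tolerance = 1e-12)
  expect_equal(erp$n_epochs, sum(keep))

  # symmetric +1/-1 epochs average to zero
  ep2 <- ep
  ep2$data[] <- rep(c(1, -1), length.out = dim(ep$data)[1])
  ep2$accepted[] <- TRUE
  ep2$labels[] <- "go"
  ep2$correct[] <- TRUE
  z <- average_erp(ep2, "go")
  expect_true(all(abs(z$data) < 1e-12))

  expect_error(average_erp(ep, "absent"), "no accepted epochs")
})

test_that("peak measurement locks every site to the reference latency", {
  # construct an ERP whose site peaks occur at different times
  times <- seq(-100, 898, by = 2)
  mat <- matrix(0, 11, length(times),
                dimnames = list(nogosim:::ALL_SITES, NULL))
  bump <- function(center, width, amp) amp * exp(-0.5 * ((times - center) / width)^2)
  mat["Fz", ] <- bump(250, 25, -5)
  mat["F3", ] <- bump(230, 25, -4)   # earlier peak elsewhere
  mat["Pz", ] <- bump(400, 40, 8)
  mat["P3", ] <- bump(450, 40, 6)
  erp <- structure(list(data = mat, times_ms = times,
                        channels = nogosim:::ALL_SITES,
                        condition = "nogo", n_epochs = 10),
                   class = "erp_waveform")
  n2 <- quantify_peak_locked(erp, "N2")
  expect_equal(n2$latency_ms, 250)
  expect_equal(n2$reference_amplitude_uv, -5)
  # F3 read at 250 ms, not at its own 230 ms peak
  expect_equal(unname(n2$amplitudes_uv["F3"]), bump(230, 25, -4)[times == 250])
  expect_false(n2$boundary)

  p3 <- quantify_peak_locked(erp, "P3")
  expect_equal(p3$latency_ms, 400)
  expect_equal(unname(p3$amplitudes_uv["Pz"]), 8)
  # P3 site read at the Pz latency, not at its own 450 ms peak
  expect_equal(unname(p3$amplitudes_uv["P3"]), bump(450, 40, 6)[times == 400])

  # a monotone trace peaks at the window endpoint and is flagged
  mat2 <- mat
  mat2["Fz", ] <- -times / 100
  erp2 <- erp; erp2$data <- mat2
  n2b <- quantify_peak_locked(erp2, "N2")
  expect_equal(n2b$latency_ms, 300)
  expect_true(n2b$boundary)

  erp3 <- erp; erp3$channels <- setdiff(erp$channels, "Fz")
  erp3$data <- mat[erp3$channels, ]
  expect_error(quantify_peak_locked(erp3, "N2"), "reference channel")
})

test_that("ties in the reference trace resolve to the earliest sample", {
  times <- seq(-100, 898, by = 2)
  mat <- matrix(0, 11, length(times),
                dimnames = list(nogosim:::ALL_SITES, NULL))
  mat["Fz", times %in% c(220, 260)] <- -3  # equal minima
  erp <- structure(list(data = mat, times_ms = times,
                        channels = nogosim:::ALL_SITES,
                        condition = "nogo", n_epochs = 1),
                   class = "erp_waveform")
  expect_equal(quantify_peak_locked(erp, "N2")$latency_ms, 220)
})

test_that("grand means average participants point-wise and check montages", {
  spec <- noiseless_spec()
  rec <- synthesize_eeg(spec, events_at(c(0, 1250, 2500)), seed = 61)
  ep <- extract_epochs(rec)
  erp <- average_erp(ep, "nogo")
  gm <- grand_mean(list(erp, erp, erp))
  expect_equal(gm$data, erp$data)

  flip <- erp; flip$data <- -erp$data
  zero <- grand_mean(list(erp, flip))
  expect_true(all(abs(zero$data) < 1e-12))

  short <- erp; short$times_ms <- erp$times_ms[-1]; short$data <- erp$data[, -1]
  expect_error(grand_mean(list(erp, short)), "mismatch")

  # brute-force mean over many synthetic participants
  set.seed(62)
  erps <- lapply(1:10, function(i) {
    e <- erp; e$data <- erp$data + rnorm(length(erp$data)); e
  })
  gm10 <- grand_mean(erps)
  expect_equal(gm10$data, Reduce(`+`, lapply(erps, `[[`, "data")) / 10,
               tolerance = 1e-12)
})

test_that("the pipeline recovers simulation parameters from noiseless data", {
  base <- noiseless_spec()
  # isolate each component so its peak is not shifted by the other's tail
  for (cmp in c("N2", "P3")) {
    spec <- base
    spec$components <- base$components[cmp]
    rec <- synthesize_eeg(spec, events_at(seq(0, 9) * 1250), seed = 71)
    ep <- reject_epochs(extract_epochs(rec))
    erp <- average_erp(ep, "nogo")
    pk <- quantify_peak_locked(erp, cmp)
    true_lat <- base$components[[cmp]]$latency_ms
    ref <- if (cmp == "N2") "Fz" else "Pz"
    expect_equal(pk$latency_ms, true_lat)
    expect_equal(unname(pk$amplitudes_uv[ref]),
                 1.25 * base$components[[cmp]]$topography[[ref]],
                 tolerance = 1e-6)
  }
})
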