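#' Specification of the auditory Go/Nogo assessment task
#'
#' Two pure tones (1100 and 2000 Hz, 200 ms) are presented at a fixed
#' interstimulus interval; participants press to the frequent Go tone
#' (70% of stimuli) and withhold to the rare Nogo tone.  Two variants
#' differ only in ISI: 2500 ms ("longer" reaction-time deadline) and
#' 1250 ms ("shorter"), the shorter ISI raising inhibitory demand.
#'
#' @param variant `"longer"` (ISI 2500 ms) or `"shorter"` (ISI 1250 ms);
#'   ignored if `isi_ms` is given directly.
#' @param n_trials Scored trials (default 100).
#' @param p_go Go proportion, realized as an exact count (default 0.70,
#'   i.e. exactly 70 Go tones of 100 in every sequence).
#' @param tone_hz_pair The two tone frequencies.
#' @param tone_duration_ms Tone duration.
#' @param isi_ms Interstimulus interval; must be 2500 or 1250.
#' @param go_tone_assignment Which element of `tone_hz_pair` is the Go
#'   tone (1 or 2); counterbalanced across participants and sessions.
#' @param n_practice Unscored practice trials (default 10).
#' @return An object of class `assessment_spec`.
#' @export
assessment_spec <- function(variant = c("longer", "shorter"),
                            n_trials = 100, p_go = 0.70,
                            tone_hz_pair = c(1100, 2000),
                            tone_duration_ms = 200,
                            isi_ms = NULL,
                            go_tone_assignment = 1,
                            n_practice = 10) {
  variant <- match.arg(variant)
  if (is.null(isi_ms)) isi_ms <- if (variant == "longer") 2500 else 1250
  if (!isi_ms %in% c(2500, 1250)) stop("isi_ms must be 2500 or 1250")
  n_go <- n_trials * p_go
  if (abs(n_go - round(n_go)) > 1e-8) {
    stop("invalid spec: n_trials * p_go must be an integer (exact counts)")
  }
  stopifnot(n_trials >= 1, p_go >= 0, p_go <= 1,
            go_tone_assignment %in% c(1, 2), n_practice >= 0)
  structure(
    list(variant = variant, n_trials = as.integer(n_trials), p_go = p_go,
         tone_hz_pair = tone_hz_pair, tone_duration_ms = tone_duration_ms,
         isi_ms = isi_ms, go_tone_assignment = go_tone_assignment,
         n_practice = as.integer(n_practice)),
    class = "assessment_spec"
  )
}

#' Generate one assessment trial sequence
#'
#' Exact-count randomization: every sequence contains exactly
#' `round(n_trials * p_go)` Go labels (never a Bernoulli draw), shuffled
#' uniformly.  Onsets are spaced exactly one ISI apart.
#'
#' @param spec An [assessment_spec()].
#' @param seed Optional integer seed.
#' @return A data.frame (`trial_sequence`) with columns `trial`, `label`
#'   (`"go"`/`"nogo"`), `onset_ms`, `tone_hz`, plus the spec as an
#'   attribute.
#' @examples
#' seq <- generate_sequence(assessment_spec("shorter"), seed = 1)
#' table(seq$label)
#' @export
generate_sequence <- function(spec = assessment_spec(), seed = NULL) {
  with_seed(seed, {
    n_go <- as.integer(round(spec$n_trials * spec$p_go))
    labels <- sample(rep(c("go", "nogo"), c(n_go, spec$n_trials - n_go)))
    go_hz <- spec$tone_hz_pair[spec$go_tone_assignment]
    nogo_hz <- spec$tone_hz_pair[3 - spec$go_tone_assignment]
    out <- data.frame(
      trial = seq_len(spec$n_trials),
      label = labels,
      onset_ms = (seq_len(spec$n_trials) - 1) * spec$isi_ms,
      tone_hz = ifelse(labels == "go", go_hz, nogo_hz),
      stringsAsFactors = FALSE
    )
    attr(out, "spec") <- spec
    class(out) <- c("trial_sequence", "data.frame")
    out
  })
}

#' Counterbalance tone assignment and task order across a roster
#'
#' The four cells (Go tone low/high x longer-/shorter-RTD task first) are
#' cycled across participants within each session, and each participant
#' receives the complementary cell in the second session, so every cell is
#' used equally often (within one) across the roster and across sessions.
#'
#' @param n_participants Roster size.
#' @param n_sessions Number of sessions (default 2).
#' @param tone_hz_pair The two tone frequencies (low, high).
#' @return A data.frame with one row per participant x session:
#'   `participant`, `session`, `go_tone_assignment` (1 = low tone is Go),
#'   `go_tone_hz`, `task_order` (`"longer_first"`/`"shorter_first"`).
#' @export
counterbalance <- function(n_participants, n_sessions = 2,
                           tone_hz_pair = c(1100, 2000)) {
  stopifnot(n_participants >= 1, n_sessions >= 1)
  cells <- expand.grid(go_tone_assignment = c(1, 2),
                       task_order = c("longer_first", "shorter_first"),
                       stringsAsFactors = FALSE)
  out <- expand.grid(participant = seq_len(n_participants),
                     session = seq_len(n_sessions))
  # Odd sessions cycle the 4 cells across the roster; even sessions give
  # each participant the complementary cell (both tone assignment and
  # task order flipped), so every cell stays balanced within sessions
  # and each participant experiences both assignments and both orders.
  base <- ((out$participant - 1) + ((out$session - 1) %/% 2)) %% 4 + 1
  idx <- ifelse(out$session %% 2 == 1, base, 5 - base)
  out$go_tone_assignment <- cells$go_tone_assignment[idx]
  out$go_tone_hz <- tone_hz_pair[out$go_tone_assignment]
  out$task_order <- cells$task_order[idx]
  out[order(out$participant, out$session), ]
}

#' Score a response stream against a trial sequence
#'
#' Each press is attributed to the most recent tone onset, with a response
#' window equal to the ISI (the de facto deadline of the task); only the
#' first press in a window counts.  A press in a Go window within the
#' window is a correct Go (latency = press time - onset); a press in a
#' Nogo window is a commission error; a Go window with no press is an
#' omission.
#'
#' Scoring is a pure function of the (sequence, responses) pair; the order
#' of the response rows is immaterial.
#'
#' @param seq A `trial_sequence` from [generate_sequence()].
#' @param responses A data.frame with column `time_ms` (press times from
#'   task start); an optional logical `pressed` column marks which rows
#'   are presses (all rows by default).
#' @return A list (`behavior_score`): `n_correct_go`, `mean_go_rt_ms`,
#'   `n_nogo_errors`, `n_omissions`, and per-trial detail in `$trials`.
#' @export
score_behavior <- function(seq, responses) {
  spec <- attr(seq, "spec")
  window <- if (!is.null(spec)) spec$isi_ms else diff(seq$onset_ms[1:2])
  times <- responses$time_ms
  if (!is.null(responses$pressed)) times <- times[responses$pressed]
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("malformed response stream: press times must be finite and >= 0")
  }
  if (length(times) && max(times) > max(seq$onset_ms) + window) {
    stop("malformed response stream: press beyond task duration")
  }
  times <- sort(times)
  hit <- findInterval(times, seq$onset_ms + 1e-9)  # window is (onset, ...]
  hit <- hit[hit >= 1]
  in_window <- times[hit >= 1] - seq$onset_ms[hit] <= window
  first_press <- tapply(times[hit >= 1][in_window], hit[in_window], min)
  pressed_trial <- rep(NA_real_, nrow(seq))
  pressed_trial[as.integer(names(first_press))] <- first_press
  rt <- pressed_trial - seq$onset_ms
  is_go <- seq$label == "go"
  correct_go <- is_go & !is.na(rt)
  out <- list(
    n_correct_go = sum(correct_go),
    mean_go_rt_ms = if (any(correct_go)) mean(rt[correct_go]) else NA_real_,
    n_nogo_errors = sum(!is_go & !is.na(rt)),
    n_omissions = sum(is_go & is.na(rt)),
    trials = data.frame(trial = seq$trial, label = seq$label,
                        rt_ms = rt,
                        correct = ifelse(is_go, !is.na(rt), is.na(rt)))
  )
  class(out) <- "behavior_score"
  out
}

#' Simulate an agent performing the assessment task
#'
#' Generates a sequence, lets the agent respond (Go tones answered with
#' probability `1 - p_omission` at a truncated-normal latency, Nogo tones
#' with probability `p_commission`), and scores the result.  Practice
#' trials are generated but excluded from scoring and from the exported
#' event markers.
#'
#' @param spec An [assessment_spec()].
#' @param agent An [agent_params()] object or preset name.
#' @param seed Optional integer seed.
#' @return A list with `sequence`, `responses` (press stream), `score`,
#'   and `events` (onset/label markers for the ERP pipeline, one per
#'   scored trial).
#' @export
simulate_assessment <- function(spec = assessment_spec(), agent = "learner",
                                seed = NULL) {
  if (is.character(agent)) agent <- agent_params(agent)
  with_seed(seed, {
    seq <- generate_sequence(spec)
    trials <- data.frame(kind = seq$label, rtd_ms = spec$isi_ms,
                         change_latency_ms = NA_real_)
    resp <- respond(agent, trials, grace_ms = 0)
    press <- data.frame(time_ms = seq$onset_ms[resp$responded] +
                          resp$rt_ms[resp$responded])
    score <- score_behavior(seq, press)
    events <- data.frame(onset_ms = seq$onset_ms, label = seq$label,
                         task = spec$variant,
                         correct = score$trials$correct,
                         stringsAsFactors = FALSE)
    list(sequence = seq, responses = press, score = score, events = events)
  })
}
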