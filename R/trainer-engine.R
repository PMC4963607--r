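#' Schedule one training game
#'
#' Draws the game's Go proportion uniformly from `go_prop_range`, realizes
#' it as an integral Go count (`round(p * trials_per_game)`), carves the
#' stop trials out of the non-Go allotment
#' (`round(stop_trial_prop * n_nongo)`), and shuffles the trial order.
#' Stop trials start healthy and switch to unhealthy at a change latency
#' drawn uniformly from `stop_change_range_ms` (capped below the deadline).
#'
#' @param config A [game_config()].
#' @param state A [difficulty_state()]; supplies the deadline.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A data.frame of trials with columns `index` (0-based), `kind`
#'   (`"go"`, `"nogo"`, `"stop"`), `category` (initial image category),
#'   `rtd_ms` and `change_latency_ms` (`NA` except on stop trials).
#' @examples
#' trials <- schedule_game(game_config(), difficulty_state(1), seed = 1)
#' table(trials$kind)
#' @export
schedule_game <- function(config = game_config(),
                          state = difficulty_state(1, config),
                          seed = NULL) {
  with_seed(seed, {
    n <- config$trials_per_game
    p <- runif(1, config$go_prop_range[1], config$go_prop_range[2])
    n_go <- as.integer(round(p * n))
    n_nongo <- n - n_go
    n_stop <- as.integer(round(config$stop_trial_prop * n_nongo))
    n_nogo <- n_nongo - n_stop
    kind <- sample(rep(c("go", "nogo", "stop"), c(n_go, n_nogo, n_stop)))
    change <- rep(NA_real_, n)
    is_stop <- kind == "stop"
    if (any(is_stop)) {
      hi <- min(config$stop_change_range_ms[2], state$rtd_ms - 1)
      change[is_stop] <- runif(sum(is_stop), config$stop_change_range_ms[1], hi)
    }
    data.frame(
      index = 0:(n - 1L),
      kind = kind,
      category = ifelse(kind == "nogo", "unhealthy", "healthy"),
      rtd_ms = state$rtd_ms,
      change_latency_ms = change,
      stringsAsFactors = FALSE
    )
  })
}

#' Adjudicate responses against scheduled trials
#'
#' Pure, vectorized outcome rules:
#' * Go trial, responded within the deadline: `correct_go`; responded after
#'   the deadline or not at all: `omission`.
#' * Nogo trial: any response is a `commission`; withholding is a
#'   `correct_inhibit`.
#' * Stop trial: a response before the image changes is a `correct_go`
#'   (the image was still healthy); at or after the change, `commission`;
#'   withholding is a `correct_inhibit`.
#'
#' @param trials Data.frame of trials as from [schedule_game()].
#' @param responded Logical vector, one per trial.
#' @param rt_ms Numeric latencies, `NA` where `responded` is `FALSE`;
#'   must lie in `(0, rtd_ms + grace_ms]` where present.
#' @param grace_ms Registration tolerance beyond the deadline.
#' @return `trials` with columns `responded`, `rt_ms`, `outcome` appended.
#' @export
adjudicate <- function(trials, responded, rt_ms, grace_ms = 150) {
  n <- nrow(trials)
  stopifnot(length(responded) == n, length(rt_ms) == n)
  if (any(responded != !is.na(rt_ms))) {
    stop("rt_ms must be present exactly when responded is TRUE")
  }
  has_rt <- !is.na(rt_ms)
  if (any(rt_ms[has_rt] <= 0) ||
      any(rt_ms[has_rt] > trials$rtd_ms[has_rt] + grace_ms)) {
    stop("malformed response latency: rt_ms outside (0, rtd_ms + grace]")
  }
  outcome <- character(n)
  go <- trials$kind == "go"
  nogo <- trials$kind == "nogo"
  stp <- trials$kind == "stop"
  in_time <- responded & rt_ms <= trials$rtd_ms
  outcome[go] <- ifelse(in_time[go], "correct_go", "omission")
  outcome[nogo] <- ifelse(responded[nogo], "commission", "correct_inhibit")
  pre_change <- responded & rt_ms < trials$change_latency_ms
  outcome[stp] <- ifelse(!responded[stp], "correct_inhibit",
                         ifelse(pre_change[stp] & in_time[stp],
                                "correct_go", "commission"))
  trials$responded <- responded
  trials$rt_ms <- rt_ms
  trials$outcome <- outcome
  trials
}

#' Summarize adjudicated trials into one game record
#' @noRd
game_record <- function(results, game_index, level) {
  go_rt <- results$rt_ms[results$outcome == "correct_go"]
  data.frame(
    game_index = as.integer(game_index),
    level = as.integer(level),
    mean_rt_ms = if (length(go_rt)) mean(go_rt) else NA_real_,
    n_correct_go = sum(results$outcome == "correct_go"),
    n_correct_nogo = sum(results$outcome == "correct_inhibit"),
    n_errors = sum(results$outcome == "commission"),
    n_omissions = sum(results$outcome == "omission")
  )
}

#' Play a full training course with a simulated participant
#'
#' Runs `n_games` consecutive games, carrying the staircase difficulty and
#' the agent's learning state across games.  A typical course is 10 games
#' per day over 14 days (140 games).
#'
#' @param agent An agent from [agent_params()].
#' @param config A [game_config()].
#' @param n_games Number of games to play.
#' @param participant_id Identifier recorded in the log.
#' @param seed Optional integer seed.
#' @return A `training_log`: a data.frame with one row per game
#'   (`participant_id`, `game_index`, `level`, `mean_rt_ms`,
#'   `n_correct_go`, `n_correct_nogo`, `n_errors`, `n_omissions`).
#' @examples
#' log <- run_course(agent_params("learner"), n_games = 20, seed = 1)
#' head(log)
#' @export
run_course <- function(agent, config = game_config(), n_games = 140,
                       participant_id = "P01", seed = NULL) {
  with_seed(seed, {
    state <- difficulty_state(1, config)
    records <- vector("list", n_games)
    for (g in seq_len(n_games)) {
      trials <- schedule_game(config, state)
      resp <- respond(agent, trials, grace_ms = config$grace_ms)
      results <- adjudicate(trials, resp$responded, resp$rt_ms,
                            grace_ms = config$grace_ms)
      records[[g]] <- game_record(results, g, state$level)
      state <- update_difficulty(state, records[[g]], config)
      agent <- learn(agent)
    }
    log <- do.call(rbind, records)
    log <- cbind(participant_id = participant_id, log)
    class(log) <- c("training_log", "data.frame")
    log
  })
}

#' Simulate a roster of training participants
#'
#' Each participant plays an independent course with a per-participant RNG
#' substream derived from `seed`, so any participant's log is reproducible
#' without replaying the others.
#'
#' @param n_participants Number of simulated players.
#' @param agent Agent preset name or an [agent_params()] object.
#' @param config A [game_config()].
#' @param games_per_day,days Course length definition (default 10 x 14).
#' @param p_full_adherence Probability a participant completes the full
#'   course; otherwise the number of games played is uniform on
#'   `[20, course length - 1]`, emulating partial adherence.
#' @param seed Optional integer seed.
#' @return A combined `training_log` data.frame for all participants.
#' @export
simulate_training <- function(n_participants = 24, agent = "learner",
                              config = game_config(), games_per_day = 10,
                              days = 14, p_full_adherence = 0.8,
                              seed = NULL) {
  if (is.character(agent)) agent <- agent_params(agent)
  with_seed(seed, {
    course_len <- games_per_day * days
    sub_seeds <- sample.int(.Machine$integer.max, n_participants)
    full <- runif(n_participants) < p_full_adherence
    n_games <- ifelse(full, course_len,
                      sample(20:(course_len - 1), n_participants,
                             replace = TRUE))
    logs <- lapply(seq_len(n_participants), function(i) {
      run_course(agent, config, n_games[i],
                 participant_id = sprintf("P%02d", i), seed = sub_seeds[i])
    })
    out <- do.call(rbind, logs)
    class(out) <- c("training_log", "data.frame")
    out
  })
}

#' Retain participants meeting the adherence cutoff
#'
#' Participants who played fewer than `cutoff` games (default 90, a 65%
#' adherence rate against the expected 140) are excluded from analysis.
#'
#' @param log A training log covering one or more participants.
#' @param cutoff Minimum number of games to be retained.
#' @return The log restricted to retained participants.
#' @export
filter_adherence <- function(log, cutoff = 90) {
  counts <- table(log$participant_id)
  keep <- names(counts)[counts >= cutoff]
  out <- log[log$participant_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign games to consecutive session blocks
#'
#' Splits `n` games into `k` consecutive blocks whose sizes differ by at
#' most one, with remainders assigned to the earliest blocks (so 120 games
#' split as 1-40, 41-80, 81-120, and 91 games split 31/30/30).
#'
#' @param n Number of games.
#' @param k Number of session blocks.
#' @return An integer vector of length `n` with block labels `1..k`.
#' @export
session_blocks <- function(n, k = 3) {
  if (n < k) stop("insufficient data: need at least ", k, " games")
  sizes <- rep(n %/% k, k)
  rem <- n %% k
  if (rem > 0) sizes[seq_len(rem)] <- sizes[seq_len(rem)] + 1L
  rep(seq_len(k), sizes)
}

#' Split one participant's log into session blocks
#'
#' @param log A `training_log` for a single participant, ordered by
#'   `game_index`.
#' @param k Number of sessions (default 3).
#' @return A list of `k` data.frames, consecutive, disjoint and exhaustive.
#' @export
split_sessions <- function(log, k = 3) {
  stopifnot(length(unique(log$participant_id)) <= 1)
  log <- log[order(log$game_index), , drop = FALSE]
  blocks <- session_blocks(nrow(log), k)
  lapply(seq_len(k), function(b) {
    out <- log[blocks == b, , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Per-session performance summary
#'
#' Averages reaction time, correct-response counts and game level within
#' each session block to yield one data point per session, the unit used
#' to assess improvement across training.
#'
#' @param blocks A list of session blocks from [split_sessions()].
#' @return A data.frame with one row per session: `session`, `n_games`,
#'   `mean_rt_ms`, `mean_correct_go`, `mean_correct_nogo`, `mean_errors`,
#'   `mean_level`.
#' @export
summarize_sessions <- function(blocks) {
  stopifnot(length(blocks) >= 1, all(vapply(blocks, nrow, 1L) > 0))
  do.call(rbind, lapply(seq_along(blocks), function(b) {
    x <- blocks[[b]]
    data.frame(
      session = b,
      n_games = nrow(x),
      mean_rt_ms = mean(x$mean_rt_ms, na.rm = TRUE),
      mean_correct_go = mean(x$n_correct_go),
      mean_correct_nogo = mean(x$n_correct_nogo),
      mean_errors = mean(x$n_errors),
      mean_level = mean(x$level)
    )
  }))
}

#' Session summaries for every participant in a log
#'
#' Applies [split_sessions()] and [summarize_sessions()] per participant
#' and stacks the results into the long table consumed by
#' [rm_anova_contrasts()].
#'
#' @inheritParams filter_adherence
#' @param k Number of sessions.
#' @return A data.frame with `participant_id`, `session` and the summary
#'   columns.
#' @export
summarize_training <- function(log, k = 3) {
  ids <- unique(log$participant_id)
  do.call(rbind, lapply(ids, function(id) {
    sub <- log[log$participant_id == id, , drop = FALSE]
    cbind(participant_id = id, summarize_sessions(split_sessions(sub, k)))
  }))
}
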