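#' Configuration for the adaptive Go/Nogo/stop training game
#'
#' Describes one "game" of the food-specific inhibitory-control training
#' task: 30 trials in which healthy-food images must be tapped before a
#' reaction-time deadline (RTD) expires, unhealthy-food images must be left
#' alone, and on stop trials an initially healthy image switches to
#' unhealthy after the timer starts, requiring cancellation of the prepared
#' response.
#'
#' Difficulty rises with the player's level along two axes: the RTD shrinks
#' (linearly from `rtd_start_ms` by `rtd_step_ms` per level down to
#' `rtd_floor_ms`) and the number of simultaneously displayed images grows
#' (one per level, capped at `max_images`).
#'
#' @param trials_per_game Number of trials in one game (default 30).
#' @param go_prop_range Closed interval of Go-trial proportions; the
#'   realized proportion is redrawn uniformly each game (default
#'   `c(0.70, 0.90)`) so players cannot pre-prepare responses.
#' @param stop_trial_prop Proportion of the non-Go allotment scheduled as
#'   stop trials (default 0.10).
#' @param max_images Maximum number of simultaneously displayed images
#'   (default 12).
#' @param rtd_start_ms,rtd_step_ms,rtd_floor_ms Reaction-time-deadline
#'   schedule: deadline at level `L` is
#'   `max(rtd_floor_ms, rtd_start_ms - rtd_step_ms * (L - 1))`.
#' @param stop_change_range_ms Interval (ms after trial onset) from which a
#'   stop trial's healthy-to-unhealthy switch latency is drawn.
#' @param promote_accuracy Minimum game accuracy
#'   (`(correct Go + correct Nogo) / trials`) required for promotion.
#' @param promote_min_inhibit Minimum number of correct inhibitions
#'   required for promotion.
#' @param grace_ms Latency tolerance beyond the RTD within which a response
#'   is still registered (but no longer counts as a correct Go).
#' @param max_level Highest attainable level; defaults to the level at
#'   which both the RTD floor and the image cap have been reached.
#' @return An object of class `game_config`.
#' @examples
#' cfg <- game_config()
#' rtd_for_level(cfg, 1:6)
#' @export
game_config <- function(trials_per_game = 30,
                        go_prop_range = c(0.70, 0.90),
                        stop_trial_prop = 0.10,
                        max_images = 12,
                        rtd_start_ms = 1000,
                        rtd_step_ms = 50,
                        rtd_floor_ms = 250,
                        stop_change_range_ms = c(100, 300),
                        promote_accuracy = 0.85,
                        promote_min_inhibit = 1,
                        grace_ms = 150,
                        max_level = NULL) {
  stopifnot(
    trials_per_game >= 1,
    length(go_prop_range) == 2,
    go_prop_range[1] >= 0, go_prop_range[2] <= 1,
    go_prop_range[1] <= go_prop_range[2],
    stop_trial_prop >= 0, stop_trial_prop <= 1,
    max_images >= 1,
    rtd_start_ms > 0, rtd_step_ms >= 0, rtd_floor_ms > 0,
    rtd_floor_ms <= rtd_start_ms,
    grace_ms >= 0
  )
  if (trials_per_game - round(go_prop_range[1] * trials_per_game) < 1) {
    stop("config leaves no non-Go trial at the minimum Go proportion")
  }
  level_rtd_max <- if (rtd_step_ms > 0) {
    ceiling((rtd_start_ms - rtd_floor_ms) / rtd_step_ms) + 1
  } else {
    1
  }
  cfg <- list(
    trials_per_game = as.integer(trials_per_game),
    go_prop_range = as.numeric(go_prop_range),
    stop_trial_prop = stop_trial_prop,
    max_images = as.integer(max_images),
    rtd_start_ms = rtd_start_ms,
    rtd_step_ms = rtd_step_ms,
    rtd_floor_ms = rtd_floor_ms,
    stop_change_range_ms = as.numeric(stop_change_range_ms),
    promote_accuracy = promote_accuracy,
    promote_min_inhibit = promote_min_inhibit,
    grace_ms = grace_ms,
    max_level = as.integer(max_level %||% max(level_rtd_max, max_images))
  )
  class(cfg) <- "game_config"
  cfg
}

#' Reaction-time deadline for a given level
#'
#' Non-increasing in level: the schedule tightens by `rtd_step_ms` per
#' level until it reaches `rtd_floor_ms`.
#' @param config A [game_config()].
#' @param level Positive integer level(s).
#' @return Deadline(s) in ms.
#' @export
rtd_for_level <- function(config, level) {
  stopifnot(all(level >= 1))
  pmax(config$rtd_floor_ms,
       config$rtd_start_ms - config$rtd_step_ms * (level - 1))
}

#' Difficulty state at a given level
#'
#' The number of simultaneously displayed images equals the level, capped
#' at `max_images`; the deadline follows the RTD schedule.
#' @param level Positive integer level.
#' @param config A [game_config()].
#' @return A list with `level`, `rtd_ms` and `n_images`.
#' @export
difficulty_state <- function(level = 1L, config = game_config()) {
  stopifnot(level >= 1)
  structure(
    list(
      level = as.integer(level),
      rtd_ms = rtd_for_level(config, level),
      n_images = min(as.integer(level), config$max_images)
    ),
    class = "difficulty_state"
  )
}

#' Staircase promotion rule
#'
#' Promotes to the next level when the completed game's accuracy reaches
#' `promote_accuracy` and at least `promote_min_inhibit` correct
#' inhibitions occurred; levels never decrease and never exceed
#' `max_level`.
#'
#' @param state A [difficulty_state()].
#' @param last_game One game record (a one-row data.frame or list with
#'   `n_correct_go`, `n_correct_nogo`).
#' @param config A [game_config()].
#' @return The updated [difficulty_state()].
#' @export
update_difficulty <- function(state, last_game, config = game_config()) {
  acc <- (last_game$n_correct_go + last_game$n_correct_nogo) /
    config$trials_per_game
  promote <- acc >= config$promote_accuracy &&
    last_game$n_correct_nogo >= config$promote_min_inhibit &&
    state$level < config$max_level
  difficulty_state(state$level + as.integer(promote), config)
}
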