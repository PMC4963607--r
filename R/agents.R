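#' Simulated participants for the training and assessment tasks
#'
#' An agent is a small parametric response model: Go-trial latencies are
#' drawn from a truncated normal, Go trials are missed with probability
#' `p_omission`, and inhibition fails (a Nogo/stop stimulus is answered)
#' with probability `p_commission`.  Learning is modelled as per-game
#' multiplicative decay of the latency mean and of the commission
#' probability towards floors, which is sufficient to reproduce the
#' qualitative training trajectory (reaction times fall, correct Go and
#' Nogo counts rise across sessions).
#'
#' Presets:
#' * `"learner"` — starts slow and error-prone and improves every game;
#'   the default for training simulations.
#' * `"static"` — no learning; useful as a null model for flat session
#'   trends.
#' * `"fast-guesser"` — fast but heavily disinhibited, no learning.
#'
#' @param preset Preset name, or `"custom"` to take every field from the
#'   arguments.
#' @param rt_mean_ms,rt_sd_ms Go-latency distribution (ms).
#' @param p_commission Probability of failing to inhibit on a Nogo/stop
#'   stimulus.
#' @param p_omission Probability of missing a Go stimulus.
#' @param learning_rate_rt Per-game multiplicative decay of `rt_mean_ms`
#'   (1 = no learning).
#' @param learning_rate_inhib Per-game multiplicative decay of
#'   `p_commission`.
#' @param learning_rate_omission Per-game multiplicative decay of
#'   `p_omission`: novices miss Go stimuli (mis-taps on the image grid,
#'   late orientation) far more often than practiced players, and this is
#'   what lets correct-Go counts rise while the staircase keeps tightening
#'   the deadline.
#' @param rt_floor_ms,p_commission_floor,p_omission_floor Lower bounds the
#'   decays respect.
#' @param rt_min_ms Physiological lower truncation for latencies.
#' @return An object of class `nogo_agent`.
#' @examples
#' a <- agent_params("learner")
#' a$rt_mean_ms
#' @export
agent_params <- function(preset = c("learner", "static", "fast-guesser",
                                    "custom"),
                         rt_mean_ms = 430, rt_sd_ms = 45,
                         p_commission = 0.30, p_omission = 0.45,
                         learning_rate_rt = 0.9926,
                         learning_rate_inhib = 0.985,
                         learning_rate_omission = 0.985,
                         rt_floor_ms = 190, p_commission_floor = 0.03,
                         p_omission_floor = 0.02,
                         rt_min_ms = 100) {
  preset <- match.arg(preset)
  if (preset == "static") {
    learning_rate_rt <- 1
    learning_rate_inhib <- 1
    learning_rate_omission <- 1
    rt_mean_ms <- 400
    p_commission <- 0.35
    p_omission <- 0.05
  } else if (preset == "fast-guesser") {
    learning_rate_rt <- 1
    learning_rate_inhib <- 1
    learning_rate_omission <- 1
    rt_mean_ms <- 250
    rt_sd_ms <- 40
    p_commission <- 0.70
    p_omission <- 0.02
  }
  stopifnot(
    rt_mean_ms > 0, rt_sd_ms > 0,
    p_commission >= 0, p_commission <= 1,
    p_omission >= 0, p_omission <= 1,
    learning_rate_rt > 0, learning_rate_rt <= 1,
    learning_rate_inhib > 0, learning_rate_inhib <= 1,
    learning_rate_omission > 0, learning_rate_omission <= 1,
    rt_floor_ms > 0, p_commission_floor >= 0, p_omission_floor >= 0
  )
  structure(
    list(
      preset = preset,
      rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
      p_commission = p_commission, p_omission = p_omission,
      learning_rate_rt = learning_rate_rt,
      learning_rate_inhib = learning_rate_inhib,
      learning_rate_omission = learning_rate_omission,
      rt_floor_ms = rt_floor_ms,
      p_commission_floor = p_commission_floor,
      p_omission_floor = p_omission_floor,
      rt_min_ms = rt_min_ms
    ),
    class = "nogo_agent"
  )
}

#' Generate an agent's responses to a set of scheduled trials
#'
#' Go trials are answered with probability `1 - p_omission` at a
#' truncated-normal latency.  On Nogo trials the agent taps with
#' probability `p_commission`.  On stop trials the agent always prepares a
#' response: if its sampled latency lands before the healthy-to-unhealthy
#' change it taps (a legitimate Go response to the still-healthy image);
#' if the change pre-empts the tap, inhibition succeeds except with
#' probability `p_commission`.
#'
#' @param agent An [agent_params()] object.
#' @param trials Trial data.frame from [schedule_game()] (or an assessment
#'   sequence recoded to `kind`/`rtd_ms` columns).
#' @param grace_ms Registration window beyond the deadline.
#' @return A data.frame with columns `responded` and `rt_ms`.
#' @export
respond <- function(agent, trials, grace_ms = 150) {
  n <- nrow(trials)
  upper <- trials$rtd_ms + grace_ms
  # One latency and one uniform per trial keeps the RNG stream aligned
  # regardless of trial kinds, so substream reproducibility is exact.
  lat <- rtruncnorm(n, agent$rt_mean_ms, agent$rt_sd_ms,
                    agent$rt_min_ms, upper)
  u <- runif(n)
  responded <- logical(n)
  go <- trials$kind == "go"
  nogo <- trials$kind == "nogo"
  stp <- trials$kind == "stop"
  responded[go] <- u[go] >= agent$p_omission
  responded[nogo] <- u[nogo] < agent$p_commission
  if (any(stp)) {
    pre <- lat < trials$change_latency_ms
    responded[stp] <- (pre[stp] & u[stp] >= agent$p_omission) |
      (!pre[stp] & u[stp] < agent$p_commission)
  }
  data.frame(responded = responded,
             rt_ms = ifelse(responded, lat, NA_real_))
}

#' Advance an agent's learning state by one game
#'
#' Applies the multiplicative decays, respecting the floors:
#' `rt_mean' = max(rt_floor_ms, rt_mean * learning_rate_rt)` and
#' `p_commission' = max(floor, p_commission * learning_rate_inhib)`.
#'
#' @param agent An [agent_params()] object.
#' @return The updated agent.
#' @export
learn <- function(agent) {
  agent$rt_mean_ms <- max(agent$rt_floor_ms,
                          agent$rt_mean_ms * agent$learning_rate_rt)
  agent$p_commission <- max(agent$p_commission_floor,
                            agent$p_commission * agent$learning_rate_inhib)
  agent$p_omission <- max(agent$p_omission_floor,
                          agent$p_omission * agent$learning_rate_omission)
  agent
}
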