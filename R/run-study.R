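#' Configuration for an end-to-end simulated study run
#'
#' Bundles the module configurations for [run_study()].  The defaults
#' reproduce the design of the emulated trial: two arms of 26, a
#' 140-game training course for the training arm with a 90-game
#' adherence cutoff and 3 session blocks, and two assessment time points
#' with longer- and shorter-RTD auditory Go/Nogo tasks plus ERP
#' quantification.  `erp_participants` caps how many participants per
#' arm get a simulated EEG (EEG synthesis dominates the run time; the
#' statistical structure is unaffected).
#'
#' @param cohort A [cohort_spec()].
#' @param game A [game_config()].
#' @param evoked An [evoked_sim_spec()].
#' @param games_per_day,days Training course length.
#' @param adherence_cutoff Minimum games for inclusion.
#' @param n_sessions Training session blocks.
#' @param assessment_trials Trials per assessment task.
#' @param erp_participants Participants per arm simulated through the EEG
#'   pipeline (`Inf` = all).
#' @param include_eeg Disable the EEG/ERP stages entirely.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_spec(),
                       game = game_config(),
                       evoked = evoked_sim_spec(),
                       games_per_day = 10, days = 14,
                       adherence_cutoff = 90, n_sessions = 3,
                       assessment_trials = 100,
                       erp_participants = 6,
                       include_eeg = TRUE) {
  structure(
    list(cohort = cohort, game = game, evoked = evoked,
         games_per_day = games_per_day, days = days,
         adherence_cutoff = adherence_cutoff, n_sessions = n_sessions,
         assessment_trials = assessment_trials,
         erp_participants = erp_participants, include_eeg = include_eeg),
    class = "run_config"
  )
}

#' One participant-session through the assessment + ERP chain
#' @noRd
erp_session_peaks <- function(config, agent, participant, condition, time) {
  out <- list()
  for (variant in c("longer", "shorter")) {
    spec <- assessment_spec(variant, n_trials = config$assessment_trials)
    sess <- simulate_assessment(spec, agent)
    rec <- synthesize_eeg(config$evoked, sess$events)
    rec <- lowpass_filter(rec)
    ep <- reject_epochs(extract_epochs(rec))
    for (stim in c("go", "nogo")) {
      erp <- tryCatch(average_erp(ep, stim), error = function(e) NULL)
      if (is.null(erp)) next
      for (cmp in c("N2", "P3")) {
        pk <- quantify_peak_locked(erp, cmp)
        out[[length(out) + 1]] <- data.frame(
          participant = participant, condition = condition, time = time,
          rtd = variant, stimulus = stim, component = cmp,
          latency_ms = pk$latency_ms, n_epochs = erp$n_epochs,
          t(pk$amplitudes_uv),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Run a complete simulated study
#'
#' Executes the whole workflow on synthetic data under one seed:
#' cohort generation; training simulation for the training arm with
#' adherence filtering, session splitting and repeated-measures ANOVA
#' with planned contrasts on reaction time and correct-response counts;
#' assessment + EEG synthesis and N2/P3 quantification at both time
#' points for both arms; and mixed time x condition ANOVAs with simple
#' effects for every behavioural outcome.  Re-running with the same
#' config and seed reproduces the results tables byte for byte.
#'
#' @param config A [run_config()].
#' @param seed Integer seed for the whole run.
#' @param out_dir Optional directory: writes `cohort.csv`,
#'   `training_log.csv`, `session_summary.csv`, `anova_results.csv`,
#'   `peaks.csv` and `manifest.json`.
#' @return A list with `cohort`, `training_log`, `session_summary`,
#'   `training_anova`, `outcome_anova` (tidy table over all outcomes),
#'   `peaks`, `erp_anova` (P3/N2 amplitude factorial, when EEG is on) and
#'   `manifest`.
#' @export
run_study <- function(config = run_config(), seed = 1, out_dir = NULL) {
  with_seed(seed, {
    stage <- "cohort"
    result <- tryCatch({
      cohort <- generate_cohort(config$cohort)

      stage <- "training"
      n_tr <- config$cohort$n_per_condition
      log <- simulate_training(n_tr, "learner", config$game,
                               config$games_per_day, config$days)
      retained <- filter_adherence(log, config$adherence_cutoff)
      message("training: ", length(unique(retained$participant_id)), "/",
              n_tr, " participants retained at cutoff ",
              config$adherence_cutoff)
      summary_tab <- summarize_training(retained, config$n_sessions)
      training_anova <- list(
        reaction_time = rm_anova_contrasts(summary_tab, value = "mean_rt_ms"),
        correct_go = rm_anova_contrasts(summary_tab,
                                        value = "mean_correct_go"),
        correct_nogo = rm_anova_contrasts(summary_tab,
                                          value = "mean_correct_nogo")
      )

      stage <- "outcome ANOVAs"
      outcomes <- names(config$cohort$outcomes)
      outcome_anova <- do.call(rbind, lapply(outcomes, function(o) {
        tab <- rbind(
          cbind(outcome = o, mixed_anova(cohort, o)),
          cbind(outcome = o, simple_effects(cohort, o))
        )
        tab
      }))

      peaks <- NULL
      erp_anova <- NULL
      if (config$include_eeg) {
        stage <- "assessment/ERP"
        ids <- unique(cohort$participant)
        conds <- cohort$condition[match(ids, cohort$participant)]
        keep <- unlist(lapply(split(ids, conds), head,
                              config$erp_participants))
        # Assessment ability improves after training for the training arm.
        peaks <- do.call(rbind, lapply(keep, function(p) {
          cond <- conds[match(p, ids)]
          do.call(rbind, lapply(1:2, function(tp) {
            trained <- cond == "training" && tp == 2
            ag <- agent_params(if (trained) "custom" else "static",
                               rt_mean_ms = if (trained) 330 else 400,
                               p_commission = if (trained) 0.15 else 0.35)
            erp_session_peaks(config, ag, p, cond, tp)
          }))
        }))
        stage <- "ERP ANOVA"
        p3 <- peaks[peaks$component == "P3", ]
        p3_long <- do.call(rbind, lapply(c(left = "F3", mid = "Fz",
                                           right = "F4"), function(site) {
          cbind(p3[c("participant", "condition", "time", "rtd", "stimulus")],
                laterality = site, amplitude = p3[[site]])
        }))
        erp_anova <- factorial_anova(
          p3_long, dv = "amplitude", id = "participant",
          within = c("time", "stimulus", "rtd", "laterality"),
          between = "condition"
        )
      }

      manifest <- list(
        seed = seed,
        package_version = as.character(utils::packageVersion("nogosim")),
        r_version = R.version.string,
        n_per_condition = config$cohort$n_per_condition,
        adherence_cutoff = config$adherence_cutoff,
        outcomes = outcomes,
        include_eeg = config$include_eeg
      )
      list(cohort = cohort, training_log = log, retained = retained,
           session_summary = summary_tab, training_anova = training_anova,
           outcome_anova = outcome_anova, peaks = peaks,
           erp_anova = erp_anova, manifest = manifest)
    }, error = function(e) {
      stop("run_study failed at stage '", stage, "': ",
           conditionMessage(e), call. = FALSE)
    })

    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_cohort(result$cohort, file.path(out_dir, "cohort.csv"))
      write_training_log(result$training_log,
                         file.path(out_dir, "training_log.csv"))
      write_csv_precise(result$session_summary,
                        file.path(out_dir, "session_summary.csv"))
      write_anova_table(result$outcome_anova,
                        file.path(out_dir, "anova_results.csv"))
      if (!is.null(result$peaks)) {
        write_csv_precise(result$peaks, file.path(out_dir, "peaks.csv"))
      }
      jsonlite::write_json(result$manifest,
                           file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    result
  })
}
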