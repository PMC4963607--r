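#' Delimited-text readers and writers
#'
#' Every tabular object round-trips through plain CSV with a header;
#' floating values are written with 15 significant digits so a
#' write-then-read cycle reproduces the in-memory object to at least 12
#' significant digits.  Schema violations are reported with the missing
#' column names.
#' @name nogosim-io
NULL

check_schema <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("malformed ", what, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  invisible(df)
}

write_csv_precise <- function(df, path) {
  num <- vapply(df, is.double, TRUE)
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.15g", x))
  })
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
}

TRAINING_LOG_COLS <- c("participant_id", "game_index", "level", "mean_rt_ms",
                       "n_correct_go", "n_correct_nogo", "n_errors",
                       "n_omissions")

#' @rdname nogosim-io
#' @param log A `training_log` data.frame.
#' @param path,dir File or directory path.
#' @export
write_training_log <- function(log, path) {
  check_schema(log, TRAINING_LOG_COLS, "training log")
  out <- as.data.frame(log)[TRAINING_LOG_COLS]
  out$timestamp <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
  write_csv_precise(out, path)
  invisible(path)
}

#' @rdname nogosim-io
#' @export
read_training_log <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, TRAINING_LOG_COLS, "training log")
  df <- df[TRAINING_LOG_COLS]
  class(df) <- c("training_log", "data.frame")
  df
}

#' @rdname nogosim-io
#' @param events An event-marker data.frame (`onset_ms`, `label`, and
#'   optionally `task`, `correct`).
#' @export
write_events <- function(events, path) {
  check_schema(events, c("onset_ms", "label"), "events file")
  write_csv_precise(as.data.frame(events), path)
  invisible(path)
}

#' @rdname nogosim-io
#' @export
read_events <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("onset_ms", "label"), "events file")
  df
}

#' @rdname nogosim-io
#' @param cohort A long cohort table from [generate_cohort()].
#' @export
write_cohort <- function(cohort, path) {
  check_schema(cohort, c("participant", "condition", "time"), "cohort table")
  write_csv_precise(cohort, path)
  invisible(path)
}

#' @rdname nogosim-io
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_schema(df, c("participant", "condition", "time"), "cohort table")
  df
}

#' @rdname nogosim-io
#' @param tab A tidy ANOVA table.
#' @export
write_anova_table <- function(tab, path) {
  check_schema(tab, c("effect", "F", "df1", "df2", "p", "partial_eta_sq"),
               "ANOVA table")
  write_csv_precise(tab, path)
  invisible(path)
}

#' Write a continuous EEG recording as text
#'
#' Writes three files under `dir`: `signal.csv` (rows = samples, columns
#' = channels), `header.json` (channel labels, sampling rate, sample
#' count) and `events.csv` (sample index, label, optional correctness).
#'
#' @rdname nogosim-io
#' @param rec An `eeg_recording`.
#' @export
write_eeg <- function(rec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- as.data.frame(rec$signal)
  names(sig) <- rec$channels
  write_csv_precise(sig, file.path(dir, "signal.csv"))
  jsonlite::write_json(
    list(channels = rec$channels, fs_hz = rec$fs_hz,
         n_samples = nrow(rec$signal)),
    file.path(dir, "header.json"), auto_unbox = TRUE
  )
  write_csv_precise(rec$events, file.path(dir, "events.csv"))
  invisible(dir)
}

#' @rdname nogosim-io
#' @export
read_eeg <- function(dir) {
  hdr_path <- file.path(dir, "header.json")
  if (!file.exists(hdr_path)) stop("malformed EEG bundle: missing header.json")
  hdr <- jsonlite::read_json(hdr_path, simplifyVector = TRUE)
  for (f in c("channels", "fs_hz", "n_samples")) {
    if (is.null(hdr[[f]])) stop("malformed EEG header: missing field ", f)
  }
  sig <- as.matrix(read.csv(file.path(dir, "signal.csv")))
  colnames(sig) <- hdr$channels
  ev <- read.csv(file.path(dir, "events.csv"), stringsAsFactors = FALSE)
  check_schema(ev, c("sample", "label"), "EEG events file")
  rec <- list(signal = unname(sig), fs_hz = hdr$fs_hz, channels = hdr$channels,
              events = ev, blink_events = integer(0))
  colnames(rec$signal) <- hdr$channels
  class(rec) <- "eeg_recording"
  rec
}

#' Serialize an epoch set as text
#'
#' The epoch x channel x time array is flattened to `epochs.csv` (one row
#' per epoch x channel, time samples as columns) with an `index.json`
#' sidecar holding times, labels, correctness and accept/reject flags.
#'
#' @rdname nogosim-io
#' @param epochs An `epoch_set`.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(2, 1, 3)), d[1] * d[2], d[3])
  df <- data.frame(
    epoch = rep(seq_len(d[1]), each = d[2]),
    channel = rep(epochs$channels, d[1]),
    flat
  )
  names(df)[-(1:2)] <- sprintf("s%04d", seq_len(d[3]))
  write_csv_precise(df, file.path(dir, "epochs.csv"))
  jsonlite::write_json(
    list(times_ms = epochs$times_ms, channels = epochs$channels,
         fs_hz = epochs$fs_hz, labels = epochs$labels,
         correct = epochs$correct, accepted = epochs$accepted,
         reject_reason = epochs$reject_reason),
    file.path(dir, "index.json"), auto_unbox = FALSE, na = "null",
    digits = NA
  )
  invisible(dir)
}

#' @rdname nogosim-io
#' @export
read_epochs <- function(dir) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path)) stop("malformed epoch bundle: missing index.json")
  idx <- jsonlite::read_json(idx_path, simplifyVector = TRUE)
  df <- read.csv(file.path(dir, "epochs.csv"), stringsAsFactors = FALSE)
  n_ch <- length(idx$channels)
  n_ep <- max(df$epoch)
  n_t <- length(idx$times_ms)
  flat <- as.matrix(df[, -(1:2)])
  data <- aperm(array(flat, c(n_ch, n_ep, n_t)), c(2, 1, 3))
  dimnames(data) <- list(NULL, idx$channels, NULL)
  es <- list(data = data, times_ms = idx$times_ms, channels = idx$channels,
             fs_hz = idx$fs_hz, labels = idx$labels, correct = idx$correct,
             accepted = idx$accepted,
             reject_reason = as.character(idx$reject_reason))
  class(es) <- "epoch_set"
  es
}
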