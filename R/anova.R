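#' Assemble one row of a tidy ANOVA table
#'
#' Degenerate effects (zero error variance with non-zero effect variance)
#' are reported with `F = Inf` and flagged in the `degenerate` column;
#' zero effect variance over zero error variance is defined as `F = 0`.
#' @noRd
anova_row <- function(effect, ss_effect, df1, ss_error, df2) {
  if (ss_error <= 0 && ss_effect <= 0) {
    f <- 0
  } else if (ss_error <= 0) {
    f <- Inf
  } else {
    f <- (ss_effect / df1) / (ss_error / df2)
  }
  data.frame(
    effect = effect, F = f, df1 = df1, df2 = df2,
    p = if (is.infinite(f)) 0 else pf(f, df1, df2, lower.tail = FALSE),
    partial_eta_sq = partial_eta_sq(f, df1, df2),
    degenerate = is.infinite(f),
    stringsAsFactors = FALSE
  )
}

#' Partial eta squared from an F ratio
#'
#' The standard effect-size identity for ANOVA effects:
#' `eta_p^2 = F * df1 / (F * df1 + df2)`, equivalently
#' `SS_effect / (SS_effect + SS_error)`.  An infinite F maps to 1.
#'
#' @param F F ratio(s), non-negative.
#' @param df1,df2 Numerator and denominator degrees of freedom.
#' @return Effect size(s) in `[0, 1]`.
#' @examples
#' partial_eta_sq(9.87, 1, 48)   # ~0.17
#' partial_eta_sq(156.80, 2, 46) # ~0.87
#' @export
partial_eta_sq <- function(F, df1, df2) {
  stopifnot(all(F >= 0), all(df1 >= 1), all(df2 >= 1))
  ifelse(is.infinite(F), 1, F * df1 / (F * df1 + df2))
}

#' One-way ANOVA from group summary statistics
#'
#' Computes the classical between/within F ratio from per-group means,
#' standard deviations and sizes alone: the between-group sum of squares
#' from the means, the within-group sum of squares from the SDs
#' (`sum((n - 1) * sd^2)`).  On unrounded summaries this is identical to
#' [oneway_anova()] on any raw data having those summaries; on printed
#' (rounded) tables it reconstructs the reported F up to rounding error.
#'
#' @param means,sds,ns Numeric vectors, one element per group (`ns >= 2`,
#'   `sds >= 0`).
#' @return A one-row tidy ANOVA table (effect, F, df1, df2, p,
#'   partial_eta_sq, degenerate).
#' @examples
#' oneway_from_summary(c(35.2, 38.3), c(14.1, 14.8), c(26, 26))
#' @export
oneway_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, length(ns) == k,
            all(ns >= 2), all(sds >= 0))
  n_tot <- sum(ns)
  gm <- sum(ns * means) / n_tot
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((ns - 1) * sds^2)
  anova_row("group", ssb, k - 1, ssw, n_tot - k)
}

#' One-way ANOVA on raw observations
#'
#' Between/within mean-square ratio over two or more independent groups.
#' For two groups the F statistic equals the square of the pooled-variance
#' two-sample t statistic.
#'
#' @param groups A list of numeric vectors (each of length >= 2), or a
#'   single numeric vector together with `g`, a grouping factor.
#' @param g Optional grouping factor when `groups` is a vector.
#' @return A one-row tidy ANOVA table.
#' @examples
#' oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))  # F = 13.5
#' @export
oneway_anova <- function(groups, g = NULL) {
  if (!is.list(groups)) {
    stopifnot(!is.null(g), length(g) == length(groups))
    groups <- split(groups, g)
  }
  stopifnot(length(groups) >= 2,
            all(vapply(groups, length, 1L) >= 2))
  oneway_from_summary(
    vapply(groups, mean, 1.0),
    vapply(groups, sd, 1.0),
    vapply(groups, length, 1L)
  )
}

#' Reshape a long cohort table to one wide row per participant
#' @noRd
cohort_wide <- function(table, outcome, id = "participant",
                        time = "time", condition = "condition") {
  need <- c(id, time, condition, outcome)
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  times <- sort(unique(table[[time]]))
  stopifnot(length(times) == 2)
  t1 <- table[table[[time]] == times[1], c(id, condition, outcome)]
  t2 <- table[table[[time]] == times[2], c(id, outcome)]
  wide <- merge(t1, t2, by = id, suffixes = c("_t1", "_t2"))
  names(wide) <- c("id", "condition", "y1", "y2")
  n_dropped <- length(unique(table[[id]])) - nrow(wide)
  if (n_dropped > 0) {
    message(n_dropped, " participant(s) missing a time point were dropped")
  }
  wide[complete.cases(wide), , drop = FALSE]
}

#' Mixed time-by-condition ANOVA
#'
#' The 2 (time: within) x 2 (condition: between) mixed-design ANOVA used
#' to analyse pre/post outcomes of a randomized waitlist-control trial.
#' Sums of squares come from the cell-means decomposition: the
#' between-subjects stratum tests condition against subjects-within-
#' condition, and the within stratum decomposes the difference scores
#' `d = y2 - y1` into time, time x condition, and time x subjects error,
#' each with `df2 = N - 2` on complete-case data.  The interaction F is
#' identical to the squared pooled two-sample t on the difference scores.
#'
#' Participants missing a time point are dropped (with a message).
#'
#' @param table A long cohort table: one row per participant x time, with
#'   a condition column (see [generate_cohort()]).
#' @param outcome Name of the outcome column.
#' @param id,time,condition Column names of the design factors.
#' @return A tidy ANOVA table with rows `condition`, `time` and
#'   `time:condition`.
#' @export
mixed_anova <- function(table, outcome, id = "participant",
                        time = "time", condition = "condition") {
  wide <- cohort_wide(table, outcome, id, time, condition)
  groups <- split(wide, wide$condition)
  stopifnot(length(groups) == 2)
  n_g <- vapply(groups, nrow, 1L)
  if (any(n_g < 2)) stop("each condition needs at least 2 complete cases")
  n <- sum(n_g)

  # Between-subjects stratum: one-way on subject means, two scores each.
  m_i <- (wide$y1 + wide$y2) / 2
  m_g <- tapply(m_i, wide$condition, mean)
  gm <- mean(m_i)
  ss_cond <- 2 * sum(n_g * (m_g - gm)^2)
  ss_subj <- 2 * sum((m_i - m_g[as.character(wide$condition)])^2)

  # Within stratum via difference scores: y - m_i = +/- d/2.
  d <- wide$y2 - wide$y1
  d_g <- tapply(d, wide$condition, mean)
  d_bar <- mean(d)
  ss_time <- n * d_bar^2 / 2
  ss_int <- sum(n_g * (d_g - d_bar)^2) / 2
  ss_err_w <- sum((d - d_g[as.character(wide$condition)])^2) / 2

  rbind(
    anova_row("condition", ss_cond, 1, ss_subj, n - 2),
    anova_row("time", ss_time, 1, ss_err_w, n - 2),
    anova_row("time:condition", ss_int, 1, ss_err_w, n - 2)
  )
}

#' Simple effects of time within each condition
#'
#' The planned follow-up to [mixed_anova()]: the data are split by
#' condition and the effect of time is assessed within each, as a paired
#' (within-subjects) F with `df = (1, n_g - 1)` — the square of the
#' paired t statistic.
#'
#' @inheritParams mixed_anova
#' @return A tidy ANOVA table with one `time` row per condition (the
#'   `effect` column is `time|<condition>`).
#' @export
simple_effects <- function(table, outcome, id = "participant",
                           time = "time", condition = "condition") {
  wide <- cohort_wide(table, outcome, id, time, condition)
  do.call(rbind, lapply(split(wide, wide$condition), function(g) {
    if (nrow(g) < 2) stop("a condition has fewer than 2 participants")
    d <- g$y2 - g$y1
    n <- length(d)
    ss_time <- n * mean(d)^2 / 2
    ss_err <- sum((d - mean(d))^2) / 2
    row <- anova_row(paste0("time|", g$condition[1]), ss_time, 1,
                     ss_err, n - 1)
    row
  }))
}

#' Repeated-measures ANOVA over session blocks with planned contrasts
#'
#' One-way repeated-measures ANOVA on k repeated measures per participant
#' (for training data, the 3 session-block means), with uncorrected
#' degrees of freedom `(k - 1, (k - 1)(n - 1))`, plus planned contrasts
#' between adjacent sessions, each a paired comparison with
#' `df = (1, n - 1)` equal to the squared paired t.  An optional
#' Greenhouse-Geisser correction adjusts the main-effect dfs for
#' sphericity violations (off by default).
#'
#' @param scores An n x k numeric matrix (participants x sessions), or a
#'   long data.frame with `id`, `session` and `value` columns.
#' @param id,session,value Column names when `scores` is long.
#' @param gg Apply the Greenhouse-Geisser epsilon to the main effect.
#' @return A list with `main` (one-row tidy table) and `contrasts` (one
#'   row per adjacent pair).
#' @export
rm_anova_contrasts <- function(scores, id = "participant_id",
                               session = "session", value = "value",
                               gg = FALSE) {
  if (is.data.frame(scores)) {
    m <- tapply(scores[[value]], list(scores[[id]], scores[[session]]),
                identity)
    scores <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  }
  if (any(is.na(scores))) stop("every participant needs all sessions")
  n <- nrow(scores)
  k <- ncol(scores)
  stopifnot(n >= 2, k >= 2)
  m_t <- colMeans(scores)
  m_i <- rowMeans(scores)
  gm <- mean(scores)
  ss_time <- n * sum((m_t - gm)^2)
  resid <- scores - outer(m_i, rep(1, k)) - outer(rep(1, n), m_t) + gm
  ss_err <- sum(resid^2)
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  if (gg) {
    eps <- gg_epsilon(scores)
    df1 <- df1 * eps
    df2 <- df2 * eps
  }
  main <- anova_row("session", ss_time, df1, ss_err, df2)
  contrasts <- do.call(rbind, lapply(seq_len(k - 1), function(j) {
    d <- scores[, j + 1] - scores[, j]
    anova_row(sprintf("session %d vs %d", j, j + 1),
              length(d) * mean(d)^2 / 2,
              1, sum((d - mean(d))^2) / 2, length(d) - 1)
  }))
  list(main = main, contrasts = contrasts)
}

#' Greenhouse-Geisser epsilon of a repeated-measures covariance
#' @noRd
gg_epsilon <- function(scores) {
  S <- stats::cov(scores)
  k <- ncol(S)
  mean_diag <- mean(diag(S))
  mean_all <- mean(S)
  row_means <- rowMeans(S)
  num <- (k * (mean_diag - mean_all))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(row_means^2) + k^2 * mean_all^2)
  min(1, num / den)
}

#' General factorial mixed ANOVA on a measurement table
#'
#' Fits a balanced mixed factorial design — one between-subjects factor
#' and any number of within-subjects factors — via [stats::aov()] with an
#' `Error(id/within...)` stratum structure, and tidies the result into
#' the package's ANOVA-table format (effect, F, df1, df2, p, partial eta
#' squared).  This is the routine used for ERP peak amplitudes, e.g.
#' condition x time x stimulus x RTD (x laterality).
#'
#' @param data Long data.frame with one row per measurement.
#' @param dv Name of the response column.
#' @param id Name of the participant column.
#' @param within Character vector of within-subjects factor columns.
#' @param between Optional between-subjects factor column.
#' @return A tidy ANOVA table, one row per tested effect.
#' @export
factorial_anova <- function(data, dv, id, within, between = NULL) {
  for (f in c(id, within, between)) data[[f]] <- factor(data[[f]])
  fixed <- paste(c(between, within), collapse = " * ")
  err <- paste0("Error(", id, "/(", paste(within, collapse = " * "), "))")
  form <- stats::as.formula(paste(dv, "~", fixed, "+", err))
  fit <- aov(form, data = data)
  out <- list()
  for (stratum in summary(fit)) {
    tab <- stratum[[1]]
    eff <- trimws(rownames(tab))
    resid_row <- eff == "Residuals"
    if (!any(resid_row) || all(resid_row)) next
    df2 <- tab$Df[resid_row]
    if (df2 < 1) next  # error stratum exhausted; effect untestable
    ms2 <- tab$`Mean Sq`[resid_row]
    for (i in which(!resid_row)) {
      f <- if (ms2 > 0) tab$`Mean Sq`[i] / ms2 else
        if (tab$`Mean Sq`[i] > 0) Inf else 0
      out[[length(out) + 1]] <- data.frame(
        effect = eff[i], F = f, df1 = tab$Df[i], df2 = df2,
        p = if (is.infinite(f)) 0 else pf(f, tab$Df[i], df2,
                                          lower.tail = FALSE),
        partial_eta_sq = partial_eta_sq(f, tab$Df[i], df2),
        degenerate = is.infinite(f),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Left-vs-right laterality contrast on a peak-amplitude table
#'
#' Averages the left-hemisphere sites (F3, C3, P3) and right-hemisphere
#' sites (F4, C4, P4) per row of a site-wide amplitude table and tests
#' the paired left-right difference across participants.
#'
#' @param amplitudes A data.frame with one row per participant (or
#'   participant x cell) holding columns for the six lateral sites.
#' @return A one-row tidy ANOVA table for the laterality contrast.
#' @export
laterality_contrast <- function(amplitudes) {
  left <- rowMeans(amplitudes[, c("F3", "C3", "P3"), drop = FALSE])
  right <- rowMeans(amplitudes[, c("F4", "C4", "P4"), drop = FALSE])
  d <- left - right
  n <- length(d)
  stopifnot(n >= 2)
  anova_row("laterality (left vs right)", n * mean(d)^2 / 2, 1,
            sum((d - mean(d))^2) / 2, n - 1)
}
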