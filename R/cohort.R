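#' Default outcome cells for the cohort simulator
#'
#' Per-outcome cell means and SDs for each condition x time cell of a
#' two-arm waitlist-control trial, calibrated to the published group
#' means of the training study this package emulates: the Healthy Eating
#' Quiz rises under training (36.96 -> 42.42) and falls on the waitlist
#' (39.58 -> 35.88); under training, food-consumption-test healthy intake
#' rises (31.59 -> 63.17 kcal) and unhealthy intake falls
#' (234.68 -> 76.50 kcal); TFEQ cognitive restraint rises under training
#' (9.27 -> 11.5) and hunger rises on the waitlist (5.58 -> 6.88).
#' Cells the source table leaves blank (no significant change) are filled
#' with stable, plausible values.
#'
#' @return A named list; each element is a list with `means` and `sds`,
#'   both 2x2 matrices (rows: training/waitlist; columns: time 1/2).
#' @export
default_outcome_cells <- function() {
  cell <- function(m_tr, m_wl, s_tr, s_wl) {
    list(means = matrix(c(m_tr, m_wl), 2, 2, byrow = TRUE,
                        dimnames = list(c("training", "waitlist"),
                                        c("t1", "t2"))),
         sds = matrix(c(s_tr, s_wl), 2, 2, byrow = TRUE,
                      dimnames = list(c("training", "waitlist"),
                                      c("t1", "t2"))))
  }
  list(
    heq_total = cell(c(36.96, 42.42), c(39.58, 35.88),
                     c(8.45, 9.98), c(9.68, 11.24)),
    fct_healthy_kcal = cell(c(31.59, 63.17), c(45, 45),
                            c(9.47, 19.08), c(15, 15)),
    fct_unhealthy_kcal = cell(c(234.68, 76.50), c(160, 160),
                              c(74.40, 25.15), c(60, 60)),
    tfeq_restraint = cell(c(9.27, 11.5), c(10, 10),
                          c(3.38, 4.25), c(4, 4)),
    tfeq_disinhibition = cell(c(8, 8), c(8, 8), c(3, 3), c(3, 3)),
    tfeq_hunger = cell(c(6, 6), c(5.58, 6.88), c(3.5, 3.5), c(3.46, 3.56))
  )
}

#' Specification of a simulated two-arm cohort
#'
#' @param n_per_condition Participants per arm (default 26, a 52-person
#'   trial).
#' @param outcomes Named list of outcome cells as from
#'   [default_outcome_cells()].
#' @param correlation Within-participant test-retest correlation of each
#'   outcome across the two time points.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param bmi_mean,bmi_sd,bmi_min BMI distribution; the support respects
#'   the trial's BMI > 25 inclusion criterion.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_condition = 26,
                        outcomes = default_outcome_cells(),
                        correlation = 0.6,
                        age_mean = 36.48, age_sd = 14.22,
                        age_range = c(19, 61),
                        bmi_mean = 29.54, bmi_sd = 4.05, bmi_min = 25) {
  stopifnot(n_per_condition >= 2,
            correlation > -1, correlation < 1,
            age_sd > 0, bmi_sd > 0, bmi_min >= 25)
  for (o in outcomes) stopifnot(all(o$sds > 0))
  structure(
    list(n_per_condition = as.integer(n_per_condition), outcomes = outcomes,
         correlation = correlation, age_mean = age_mean, age_sd = age_sd,
         age_range = age_range, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
         bmi_min = bmi_min),
    class = "cohort_spec"
  )
}

#' Generate a synthetic randomized waitlist-control cohort
#'
#' Produces a balanced two-condition cohort in long format (one row per
#' participant x time).  Each outcome is drawn bivariate-normal across
#' the two time points at the cell means and SDs of the spec, with the
#' spec's test-retest correlation; demographics are truncated normal.
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional integer seed.
#' @return A data.frame with columns `participant`, `condition`, `age`,
#'   `bmi`, `time` (1/2) and one column per outcome.
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_condition = 8), seed = 1)
#' head(cohort)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  with_seed(seed, {
    n <- spec$n_per_condition
    conditions <- rep(c("training", "waitlist"), each = n)
    n_tot <- 2 * n
    age <- rtruncnorm(n_tot, spec$age_mean, spec$age_sd,
                      spec$age_range[1], spec$age_range[2])
    bmi <- rtruncnorm(n_tot, spec$bmi_mean, spec$bmi_sd, spec$bmi_min, Inf)
    rho <- spec$correlation
    base <- data.frame(
      participant = sprintf("S%03d", seq_len(n_tot)),
      condition = conditions, age = age, bmi = bmi,
      stringsAsFactors = FALSE
    )
    long <- rbind(cbind(base, time = 1L), cbind(base, time = 2L))
    for (nm in names(spec$outcomes)) {
      cells <- spec$outcomes[[nm]]
      z1 <- rnorm(n_tot)
      z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n_tot)
      m1 <- cells$means[conditions, "t1"]
      m2 <- cells$means[conditions, "t2"]
      s1 <- cells$sds[conditions, "t1"]
      s2 <- cells$sds[conditions, "t2"]
      long[[nm]] <- c(m1 + s1 * z1, m2 + s2 * z2)
    }
    rownames(long) <- NULL
    long
  })
}

#' Score the food consumption test from grams consumed
#'
#' Four snack bowls are offered — two healthier (unsalted nuts, grapes)
#' and two less healthy (plain potato chips, chocolate candies) — and the
#' grams eaten of each are converted to kilocalories and pooled into a
#' healthy and an unhealthy total.  Energy densities are configurable
#' constants (kcal/g), not measured study values.
#'
#' @param consumed_g Named numeric: grams consumed of `nuts`, `grapes`,
#'   `chips`, `candy`.
#' @param offered_g Portion sizes offered; consumption beyond the offered
#'   portion signals a weighing error.
#' @param kcal_per_g Energy densities.
#' @return A list with `healthy_kcal` (nuts + grapes) and
#'   `unhealthy_kcal` (chips + candy).
#' @examples
#' score_fct(c(nuts = 10, grapes = 10, chips = 10, candy = 10))
#' @export
score_fct <- function(consumed_g,
                      offered_g = c(nuts = 156, grapes = 216,
                                    chips = 60, candy = 161),
                      kcal_per_g = c(nuts = 6.07, grapes = 0.69,
                                     chips = 5.36, candy = 4.92)) {
  foods <- c("nuts", "grapes", "chips", "candy")
  stopifnot(all(foods %in% names(consumed_g)),
            all(kcal_per_g[foods] > 0))
  consumed_g <- consumed_g[foods]
  if (any(consumed_g < 0) || any(consumed_g > offered_g[foods])) {
    stop("weighing error: consumed grams outside [0, offered]")
  }
  kcal <- consumed_g * kcal_per_g[foods]
  list(healthy_kcal = unname(kcal["nuts"] + kcal["grapes"]),
       unhealthy_kcal = unname(kcal["chips"] + kcal["candy"]))
}
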