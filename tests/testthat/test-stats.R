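test_that("one-way ANOVA matches hand sums of squares and the t-squared oracle", {
  expect_equal(oneway_anova(list(c(1, 2, 3), c(4, 5, 6)))$F, 13.5)

  same <- oneway_anova(list(c(2, 3, 4), c(2, 3, 4)))
  expect_equal(same$F, 0)

  set.seed(1)
  for (i in 1:10) {
    a <- rnorm(8 + i); b <- rnorm(12, mean = 0.4)
    res <- oneway_anova(list(a, b))
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(res$p, tt$p.value, tolerance = 1e-10)
    # and against the base linear-model ANOVA for a 3-group case
    g3 <- list(a, b, rnorm(9, 1))
    y <- unlist(g3); g <- factor(rep(1:3, lengths(g3)))
    ref <- anova(lm(y ~ g))
    r3 <- oneway_anova(g3)
    expect_equal(r3$F, ref$`F value`[1], tolerance = 1e-10)
    expect_equal(r3$df2, ref$Df[2])
  }

  # degenerate: zero variance everywhere is defined as F = 0
  expect_equal(oneway_anova(list(c(1, 1), c(1, 1)))$F, 0)
  expect_true(oneway_anova(list(c(1, 1), c(2, 2)))$degenerate)
})

test_that("summary-statistic ANOVA equals the raw-data path on exact summaries", {
  set.seed(2)
  for (i in 1:10) {
    a <- rnorm(7); b <- rnorm(15, 1); c <- rnorm(10, -1)
    raw <- oneway_anova(list(a, b, c))
    summ <- oneway_from_summary(c(mean(a), mean(b), mean(c)),
                                c(sd(a), sd(b), sd(c)),
                                c(7, 15, 10))
    expect_equal(raw$F, summ$F, tolerance = 1e-10)
    expect_equal(raw$p, summ$p, tolerance = 1e-10)
  }
  expect_equal(oneway_from_summary(c(5, 5), c(1, 2), c(10, 10))$F, 0)
  expect_error(oneway_from_summary(c(1, 2), c(1, 1), c(1, 5)))
})

test_that("baseline table reconstruction from printed summaries is close to printed Fs", {
  # age row: printed F = 0.56; recomputation from 1-dp rounded summaries ~ 0.60
  age <- oneway_from_summary(c(35.2, 38.3), c(14.1, 14.8), c(26, 26))
  expect_equal(age$F, 0.60, tolerance = 0.01)
  expect_gt(age$p, 0.05)
})

test_that("the mixed ANOVA agrees with the aov() error-stratum oracle", {
  set.seed(3)
  for (i in 1:6) {
    n <- 10 + i
    cohort <- data.frame(
      participant = rep(sprintf("S%02d", 1:(2 * n)), times = 2),
      condition = rep(rep(c("training", "waitlist"), each = n), 2),
      time = rep(1:2, each = 2 * n)
    )
    subj_eff <- rnorm(2 * n)
    cohort$y <- rnorm(4 * n) + subj_eff[as.integer(factor(cohort$participant))] +
      0.5 * (cohort$time == 2) * (cohort$condition == "training")
    mine <- mixed_anova(cohort, "y")
    fit <- aov(y ~ condition * time + Error(participant),
               data = transform(cohort, time = factor(time),
                                condition = factor(condition),
                                participant = factor(participant)))
    s <- summary(fit)
    between <- s[["Error: participant"]][[1]]
    within <- s[["Error: Within"]][[1]]
    expect_equal(mine$F[mine$effect == "condition"],
                 between["condition", "F value"], tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "time"],
                 within["time", "F value"], tolerance = 1e-8)
    expect_equal(mine$F[mine$effect == "time:condition"],
                 within["condition:time", "F value"], tolerance = 1e-8)
    expect_equal(mine$df2, rep(2 * n - 2, 3))
  }
})

test_that("mixed ANOVA degenerate and incomplete cases are handled", {
  cohort <- data.frame(
    participant = rep(c("a", "b", "c", "d", "e", "f"), 2),
    condition = rep(c("t", "t", "t", "w", "w", "w"), 2),
    time = rep(1:2, each = 6),
    y = 5
  )
  out <- mixed_anova(cohort, "y")
  expect_equal(out$F, c(0, 0, 0))

  # pure +1/-1 interaction with zero noise: all within-variance is
  # interaction; flagged degenerate
  cohort$y <- rep(c(1, 1, 1, -1, -1, -1), 2) * rep(c(1, -1), each = 6)
  out2 <- mixed_anova(cohort, "y")
  int <- out2[out2$effect == "time:condition", ]
  expect_true(is.infinite(int$F))
  expect_true(int$degenerate)
  expect_equal(int$partial_eta_sq, 1)

  # a participant missing time 2 is dropped with a message
  expect_message(mixed_anova(cohort[-1, ], "y"), "dropped")
})

test_that("simple effects equal the squared paired t per condition", {
  set.seed(4)
  cohort <- generate_cohort(cohort_spec(n_per_condition = 12), seed = 5)
  out <- simple_effects(cohort, "heq_total")
  for (cond in c("training", "waitlist")) {
    sub <- cohort[cohort$condition == cond, ]
    wide <- merge(sub[sub$time == 1, c("participant", "heq_total")],
                  sub[sub$time == 2, c("participant", "heq_total")],
                  by = "participant")
    tt <- t.test(wide$heq_total.y, wide$heq_total.x, paired = TRUE)
    row <- out[out$effect == paste0("time|", cond), ]
    expect_equal(row$F, unname(tt$statistic^2), tolerance = 1e-10)
    expect_equal(row$df2, 11)
  }

  flat <- cohort
  flat$heq_total <- ave(flat$heq_total, flat$participant)
  out0 <- simple_effects(flat, "heq_total")
  expect_equal(out0$F, c(0, 0))

  shift <- cohort
  shift$heq_total <- 10 + 2 * (shift$time == 2)
  outs <- simple_effects(shift, "heq_total")
  expect_true(all(is.infinite(outs$F)))
  expect_true(all(outs$degenerate))
})

test_that("repeated-measures ANOVA reports the study dfs and matches oracles", {
  set.seed(5)
  scores <- matrix(rnorm(24 * 3, mean = rep(c(400, 330, 307), each = 24),
                         sd = 30), 24, 3)
  res <- rm_anova_contrasts(scores)
  expect_equal(c(res$main$df1, res$main$df2), c(2, 46))
  expect_equal(res$contrasts$df1, c(1, 1))
  expect_equal(res$contrasts$df2, c(23, 23))

  # main effect against the aov stratum oracle
  long <- data.frame(id = factor(rep(1:24, 3)),
                     session = factor(rep(1:3, each = 24)),
                     y = as.vector(scores))
  s <- summary(aov(y ~ session + Error(id), data = long))
  expect_equal(res$main$F, s[["Error: Within"]][[1]]["session", "F value"],
               tolerance = 1e-8)

  # contrasts equal squared paired t
  for (j in 1:2) {
    tt <- t.test(scores[, j + 1], scores[, j], paired = TRUE)
    expect_equal(res$contrasts$F[j], unname(tt$statistic^2),
                 tolerance = 1e-10)
  }

  same <- matrix(5, 10, 3)
  expect_equal(rm_anova_contrasts(same)$main$F, 0)

  expect_error(rm_anova_contrasts(matrix(c(1, 2, NA, 4, 5, 6), 2, 3)),
               "all sessions")
})

test_that("the factorial routine reproduces the dedicated 2x2 mixed ANOVA", {
  set.seed(6)
  cohort <- generate_cohort(cohort_spec(n_per_condition = 10), seed = 7)
  mine <- mixed_anova(cohort, "heq_total")
  gen <- factorial_anova(cohort, dv = "heq_total", id = "participant",
                         within = "time", between = "condition")
  expect_equal(gen$F[gen$effect == "condition:time"],
               mine$F[mine$effect == "time:condition"], tolerance = 1e-8)
  expect_equal(gen$F[gen$effect == "condition"],
               mine$F[mine$effect == "condition"], tolerance = 1e-8)
})

test_that("partial eta squared reproduces the printed effect-size triples", {
  expect_equal(round(partial_eta_sq(9.87, 1, 48), 2), 0.17)
  expect_equal(round(partial_eta_sq(156.80, 2, 46), 2), 0.87)
  expect_equal(partial_eta_sq(0, 1, 48), 0)
  expect_equal(partial_eta_sq(Inf, 1, 48), 1)
  # vectorized
  expect_equal(round(partial_eta_sq(c(8.49, 6.02), 1, c(46, 50)), 2),
               c(0.16, 0.11))
})

test_that("dependent-means power analysis is exact and consistent", {
  expect_equal(required_n_dependent_t(0.5, 0.05, 0.95), 54L)
  expect_gte(power_dependent_t(54, 0.5), 0.95)
  expect_lt(power_dependent_t(53, 0.5), 0.95)

  # huge effects bottom out at the smallest usable n
  expect_lte(required_n_dependent_t(50, 0.05, 0.95), 4L)
  expect_error(required_n_dependent_t(1e-4, n_max = 500), "unattainable")

  # alpha-level sanity: power at d = 0 equals alpha
  expect_equal(power_dependent_t(30, 0, alpha = 0.05), 0.05, tolerance = 1e-10)
})

test_that("laterality contrasts test the paired left-right difference", {
  set.seed(8)
  amp <- data.frame(F3 = rnorm(12, 2), C3 = rnorm(12, 2), P3 = rnorm(12, 2),
                    F4 = rnorm(12, 1), C4 = rnorm(12, 1), P4 = rnorm(12, 1))
  out <- laterality_contrast(amp)
  d <- rowMeans(amp[, 1:3]) - rowMeans(amp[, 4:6])
  tt <- t.test(d)
  expect_equal(out$F, unname(tt$statistic^2), tolerance = 1e-10)
  expect_equal(out$df2, 11)
})
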