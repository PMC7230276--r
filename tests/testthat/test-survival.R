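test_that("Kaplan-Meier matches hand computation and degenerate cases", {
  # times 1+, 2, 3+, 4: at t=2 three at risk, one event -> S(2) = 2/3
  k <- km_fit(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(k$surv[k$time == 2], 2 / 3)
  expect_equal(k$surv[k$time == 4], 2 / 3 * (1 - 1 / 1))
  # all censored: survival identically 1
  k0 <- km_fit(c(5, 7, 9), c(0, 0, 0))
  expect_true(all(k0$surv == 1))
  # never increases; cuminc is the complement
  set.seed(4)
  t <- rexp(100); d <- rbinom(100, 1, 0.5)
  k2 <- km_fit(t, d)
  expect_true(all(diff(k2$surv) <= 1e-12))
  expect_equal(k2$cuminc, 1 - k2$surv)
  expect_error(km_fit(c(0, 1), c(1, 1)), "positive")
})

test_that("without censoring the KM curve is the empirical survival function", {
  set.seed(8)
  t <- sample(1:40, 60, replace = TRUE)
  k <- km_fit(t, rep(1, 60))
  emp <- vapply(k$time, function(u) mean(t > u), 0)
  expect_equal(k$surv, emp, tolerance = 1e-12)
})

test_that("trend log-rank with two groups equals the standard log-rank", {
  skip_if_not_installed("survival")
  set.seed(12)
  for (i in 1:6) {
    n <- 80
    g <- rbinom(n, 1, 0.5)
    t <- rexp(n, rate = exp(0.6 * g))
    d <- rbinom(n, 1, 0.7)
    if (sum(d[g == 0]) == 0 || sum(d[g == 1]) == 0) next
    lr <- logrank_trend(t, d, factor(g))
    ref <- survival::survdiff(survival::Surv(t, d) ~ g)
    expect_equal(lr$statistic, ref$chisq, tolerance = 1e-10)
  }
})

test_that("trend log-rank is zero for identical groups and affine-invariant", {
  # identical event/censor patterns in both groups
  t <- rep(c(1, 2, 3, 4, 5), 2)
  d <- rep(c(1, 0, 1, 1, 0), 2)
  g <- rep(c("a", "b"), each = 5)
  lr <- logrank_trend(t, d, g)
  expect_equal(lr$u, 0)
  expect_equal(lr$p, 1)
  # affine transform of scores leaves the statistic unchanged
  set.seed(13)
  t <- rexp(90); d <- rbinom(90, 1, 0.7)
  g <- factor(sample(c("lo", "mid", "hi"), 90, TRUE),
              levels = c("lo", "mid", "hi"))
  s0 <- logrank_trend(t, d, g, scores = c(0, 1, 2))
  s1 <- logrank_trend(t, d, g, scores = c(10, 3, -4))  # -7x + 10
  expect_equal(s0$statistic, s1$statistic, tolerance = 1e-10)
  expect_error(logrank_trend(t, d, g, scores = c(1, 2)), "one score per group")
  expect_error(logrank_trend(rep(1, 4), rep(1, 4), rep("a", 4)), "two groups")
})

test_that("cox_fit maximises the partial likelihood (grid-search oracle)", {
  fx <- six_subject_fixture()
  fit <- cox_fit(fx$time, fx$event, fx$x)
  # two-stage 1-D grid on the explicit partial likelihood
  grid <- seq(-4, 4, by = 0.001)
  ll <- vapply(grid, partial_loglik, 0, time = fx$time, event = fx$event,
               x = fx$x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.002, b0 + 0.002, by = 1e-5)
  llf <- vapply(fine, partial_loglik, 0, time = fx$time, event = fx$event,
                x = fx$x)
  expect_lt(abs(fit$coefficients$beta - fine[which.max(llf)]), 1e-4)
  expect_true(fit$converged)
})

test_that("cox_fit agrees with the reference implementation on random data", {
  skip_if_not_installed("survival")
  set.seed(21)
  for (i in 1:6) {
    n <- 70
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.4))
    tied <- i %% 2 == 0
    t <- if (tied) sample(1:10, n, TRUE) else rexp(n, exp(0.4 * x[, 1]))
    d <- rbinom(n, 1, 0.6)
    for (ties in c("breslow", "efron")) {
      fit <- cox_fit(t, d, x, ties = ties)
      ref <- survival::coxph(survival::Surv(t, d) ~ x, ties = ties)
      expect_equal(fit$coefficients$beta, unname(coef(ref)), tolerance = 1e-6)
      expect_equal(fit$coefficients$se, unname(sqrt(diag(vcov(ref)))),
                   tolerance = 1e-6)
    }
  }
})

test_that("cox score test at zero equals the log-rank statistic (untied)", {
  set.seed(31)
  for (i in 1:5) {
    n <- 60
    g <- rbinom(n, 1, 0.5)
    t <- rexp(n, exp(0.5 * g))
    d <- rbinom(n, 1, 0.7)
    if (length(unique(g)) < 2 || sum(d) < 3) next
    fit <- cox_fit(t, d, g)
    lr <- logrank_trend(t, d, factor(g))
    expect_equal(fit$score_test$statistic, lr$statistic, tolerance = 1e-8)
  }
})

test_that("cox estimates are shift-invariant in the covariate", {
  set.seed(41)
  n <- 100
  z <- rexp(n, 1 / 10)
  t <- rexp(n, 0.01 * exp(0.1 * z))
  d <- rbinom(n, 1, 0.8)
  f1 <- cox_fit(t, d, z)
  f2 <- cox_fit(t, d, z + 100)
  expect_equal(f1$coefficients$beta, f2$coefficients$beta, tolerance = 1e-8)
  expect_equal(f1$coefficients$hr, f2$coefficients$hr, tolerance = 1e-8)
})

test_that("degenerate covariates are caught", {
  fx <- six_subject_fixture()
  expect_error(cox_fit(fx$time, fx$event, rep(1, 6)), "constant")
  expect_error(cox_fit(fx$time, fx$event, cbind(fx$x, fx$x)), "singular")
  expect_error(cox_fit(fx$time, rep(0, 6), fx$x), "at least one event")
  # monotone likelihood: all events carry x = 1 and occur before any x = 0
  # subject leaves the risk set in the opposite direction
  t <- c(1, 2, 3, 10, 11, 12)
  d <- c(1, 1, 1, 0, 0, 0)
  x <- c(1, 1, 1, 0, 0, 0)
  expect_warning(fit <- cox_fit(t, d, x), "monotone")
  expect_false(fit$converged)
  expect_lte(abs(fit$coefficients$beta), 15)
})

test_that("parameter recovery: per-point HR on simulated cohorts is unbiased", {
  spec <- cohort_spec()
  betas <- vapply(1:120, function(i) {
    co <- simulate_cohort(spec, seed = 500 + i)
    cox_fit(co$time_days, co$event, co$hfs - 100)$coefficients$beta
  }, 0)
  mcse <- sd(betas) / sqrt(length(betas))
  expect_lt(abs(mean(betas) - log(1.16)), 3 * mcse)
})

test_that("cox_table flags zero-event levels as n/c and keeps the rest", {
  spec <- cohort_spec(n = 150)
  co <- simulate_cohort(spec, seed = 9)
  # force a zero-event stratum: move all stage I/II events elsewhere
  co$stage[co$event == 1 & co$stage %in% c("I", "II")] <- "III"
  tab <- cox_table(co, variables = c("stage", "hfs"))
  i_ii <- tab[tab$term == "stage_I_II", ]
  expect_equal(i_ii$note, "n/c")
  expect_true(is.na(i_ii$hr))
  hfs_row <- tab[tab$term == "hfs", ]
  expect_false(is.na(hfs_row$hr))
  expect_gt(hfs_row$hr, 1)
})

test_that("replaced multiple: independent adjuster leaves the HFS HR stable", {
  spec <- cohort_spec()
  co <- simulate_cohort(spec, seed = 77)
  simple <- cox_fit(co$time_days, co$event, co$hfs - 100)
  rm_tab <- replaced_multiple(co, adjusters = c("radiation", "gs"))
  expect_equal(rm_tab$adjuster, c("none", "radiation", "gs"))
  expect_equal(rm_tab$hr[1], simple$coefficients$hr, tolerance = 1e-10)
  # adjusters were generated independently of both HFS and the hazard:
  # the HFS estimate moves by far less than one standard error
  se <- simple$coefficients$se
  expect_lt(max(abs(log(rm_tab$hr) - log(rm_tab$hr[1]))), se)
})

test_that("replaced multiple with a copy of HFS is singular", {
  spec <- cohort_spec(n = 100)
  co <- simulate_cohort(spec, seed = 5)
  expect_error(cox_fit(co$time_days, co$event,
                       cbind(hfs = co$hfs - 100, copy = co$hfs - 100)),
               "singular")
})
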