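test_that("cohort simulation is exactly reproducible given (spec, seed)", {
  spec <- cohort_spec()
  a <- simulate_cohort(spec, seed = 42)
  b <- simulate_cohort(spec, seed = 42)
  attr(a, "spec") <- NULL; attr(b, "spec") <- NULL
  expect_identical(a, b)
  c2 <- simulate_cohort(spec, seed = 43)
  expect_false(identical(a$time_days, c2$time_days))
})

test_that("simulated cohorts respect the spec's structure", {
  spec <- cohort_spec()
  co <- simulate_cohort(spec, seed = 7)
  expect_equal(nrow(co), 214)
  expect_true(all(co$time_days > 0))
  expect_true(all(co$event %in% 0:1))
  expect_true(all(co$censor_reason[co$event == 1] == "none"))
  expect_true(all(co$censor_reason %in%
                    c("death", "transfer", "lost", "ici_initiation",
                      "admin_end", "none")))
  # HFS: point mass at 100 plus the mild band, on the 5/6 lattice
  expect_true(all(co$hfs >= 100 & co$hfs <= 200))
  k <- (co$hfs - 100) * 6 / 5
  expect_true(all(abs(k - round(k)) < 1e-9))
  expect_true(all(co$gs >= 0 & co$gs <= 24))
})

test_that("covariate marginals converge to the spec at large n", {
  spec <- cohort_spec(n = 20000)
  co <- simulate_cohort(spec, seed = 11)
  tol3 <- function(p, n) 3 * sqrt(p * (1 - p) / n)
  n <- nrow(co)
  expect_lt(abs(mean(co$hfs > 100) - spec$p_ild), tol3(spec$p_ild, n))
  expect_lt(abs(mean(co$sex == "male") - spec$p_male), tol3(spec$p_male, n))
  expect_lt(abs(mean(co$smoking == "ever") - spec$p_ever_smoker),
            tol3(spec$p_ever_smoker, n))
  expect_lt(abs(mean(co$histology == "adenocarcinoma") -
                  spec$p_histology[["adenocarcinoma"]]), 0.01)
  expect_lt(abs(mean(co$stage == "IV_recurrence") -
                  spec$p_stage[["IV_recurrence"]]), 0.01)
  # mean HFS excess among ILD patients near the truncated-exponential mean
  lat <- hfs_excess_lattice(spec)
  expect_lt(abs(mean(co$hfs[co$hfs > 100] - 100) -
                  sum(lat$excess * lat$prob)), 0.5)
})

test_that("event fraction is calibrated to the target", {
  spec <- cohort_spec()
  events <- vapply(1:20, function(i) sum(simulate_cohort(spec, seed = i)$event), 0)
  n_tot <- 20 * spec$n
  phat <- sum(events) / n_tot
  tol3 <- 3 * sqrt(spec$target_event_fraction *
                     (1 - spec$target_event_fraction) / n_tot)
  expect_lt(abs(phat - spec$target_event_fraction), tol3)
})

test_that("a null HFS effect produces no association with the stratum", {
  spec <- cohort_spec(beta_hfs = 0, n = 3000)
  co <- simulate_cohort(spec, seed = 23)
  tab <- table(ild = co$hfs > 100, event = co$event)
  expect_gt(chisq_2x2(tab)$p, 0.001)
})

test_that("zero-noise reads reconstruct every target exactly, ICC = 1", {
  spec <- cohort_spec(n = 120)
  co <- simulate_cohort(spec, seed = 3)
  reads <- simulate_reads(co, reader_noise_spec(noise_sd = 0), seed = 4)
  sc <- reader_scores(reads)
  ps <- patient_scores(sc)
  ps <- ps[match(co$patient_id, ps$patient_id), ]
  expect_equal(ps$hfs, co$hfs, tolerance = 1e-9)
  expect_equal(ps$gs, as.numeric(co$gs))
  m <- ratings_matrix(sc, "hfs")
  expect_equal(unname(m[, 1]), unname(m[, 2]))
  expect_equal(icc(m)$estimate, 1)
  # patients without ILD are read as fully normal
  normal_ids <- co$patient_id[co$hfs == 100]
  norm_reads <- reads[reads$patient_id %in% normal_ids, ]
  expect_true(all(norm_reads$pct_normal == 100))
})

test_that("calibrated noise hits the requested population ICC exactly", {
  spec <- cohort_spec()
  co <- simulate_cohort(spec, seed = 31)
  reads <- simulate_reads(co, reader_noise_spec(icc_target = 0.96), seed = 32)
  expect_equal(attr(reads, "population_icc"), 0.96, tolerance = 1e-10)
  # implied variance identity
  vh <- var(co$hfs)
  expect_equal(attr(reads, "noise_var"), vh * 0.04 / 0.96, tolerance = 1e-8)
  # reads are valid scorable partitions for both readers
  sc <- reader_scores(reads)
  expect_equal(nrow(sc), 2 * nrow(co))
  expect_true(all(sc$hfs >= 100 & sc$hfs <= 400))
})

test_that("unreachable targets are rejected, naming the patient", {
  co <- data.frame(patient_id = c("ok", "bad"), hfs = c(105, 103), gs = c(0, 0))
  expect_error(simulate_reads(co, reader_noise_spec(noise_sd = 0), seed = 1),
               "bad")
})

test_that("invalid specs are rejected", {
  expect_error(cohort_spec(p_ild = 1.2), "probabilities")
  expect_error(cohort_spec(n = 1), "at least 2")
  expect_error(cohort_spec(p_histology = c(adenocarcinoma = 1, squamous = 0.5,
                                           small_cell = 0, other = 0)),
               "sum to 1")
  expect_error(cohort_spec(target_event_fraction = 0), "calibrate")
})

test_that("baseline-hazard calibration solves the closed-form event fraction", {
  spec <- cohort_spec()
  lat <- hfs_excess_lattice(spec)
  expect_equal(sum(lat$prob), 1, tolerance = 1e-12)
  pe <- function(z) {
    theta <- spec$baseline_hazard * exp(spec$beta_hfs * z)
    mu <- 1 / spec$dropout_mean
    theta / (theta + mu) * (1 - exp(-(theta + mu) * spec$admin_horizon))
  }
  marginal <- (1 - spec$p_ild) * pe(0) + spec$p_ild * sum(lat$prob * pe(lat$excess))
  expect_equal(marginal, spec$target_event_fraction, tolerance = 1e-10)
})
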