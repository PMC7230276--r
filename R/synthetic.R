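# Synthetic cohort and reader-read generation.
#
# The generator reproduces the statistical structure the downstream analysis
# assumes: a cohort in which ~28.5% of patients carry mild pre-existing ILD
# (HFS in the (100, 200] band, the rest exactly 100), an event hazard
# log-linear in (HFS - 100), right censoring from death/transfer/loss/ICI
# plus an administrative horizon, covariate marginals matching a mixed-stage
# lung-cancer chemotherapy population, and two-reader scoring noise with a
# known population intraclass correlation.

HFS_LATTICE_STEP <- 5 / 6  # one 5% extent step in one of six regions

#' Cohort simulation specification
#'
#' Collects the parameters of the synthetic cohort. Defaults encode the
#' study conditions the analysis is designed for: n = 214 patients, ILD
#' prevalence 28.5%, HFS excess (HFS - 100) for ILD patients following an
#' exponential with mean 15 points truncated to (0, 100] and discretised to
#' the 5/6-point lattice reachable by six-region 5%-grid arithmetic, a true
#' per-point hazard ratio of 1.16 for the HFS effect, and a marginal event
#' fraction of 19/214 (~8.9%) obtained by calibrating the baseline
#' exponential hazard in closed form. Censoring combines an administrative
#' horizon (1460 days) with exponential dropout (mean 365 days) split among
#' death, hospital transfer, loss to follow-up and immune-checkpoint
#' inhibitor initiation.
#'
#' @param n Cohort size.
#' @param p_ild Probability of pre-existing ILD (HFS > 100).
#' @param hfs_excess_mean,hfs_excess_max Mean and truncation bound (points)
#'   of the exponential HFS-excess distribution given ILD.
#' @param beta_hfs True log hazard ratio per HFS point.
#' @param baseline_hazard Baseline event hazard per day for an HFS-100
#'   patient; `NULL` (default) calibrates it so the expected event fraction
#'   equals `target_event_fraction`.
#' @param target_event_fraction Marginal event probability used for
#'   calibration.
#' @param admin_horizon Administrative censoring horizon, days.
#' @param dropout_mean Mean of the exponential dropout time, days.
#' @param p_male,p_ever_smoker,p_ps_2_4,p_gene_abnormality,p_operation,p_radiation
#'   Bernoulli covariate marginals.
#' @param p_histology,p_stage,p_gs_category Multinomial covariate marginals
#'   (named, summing to 1).
#' @param age_mean,age_sd,age_range Age distribution (normal, rounded,
#'   clipped to the range).
#' @param censor_reason_probs Probabilities of death / transfer / lost /
#'   ici_initiation given non-administrative censoring.
#' @return Object of class `"cohort_spec"` (a list), with
#'   `baseline_hazard` filled in.
#' @export
cohort_spec <- function(n = 214,
                        p_ild = 0.285,
                        hfs_excess_mean = 15,
                        hfs_excess_max = 100,
                        beta_hfs = log(1.16),
                        baseline_hazard = NULL,
                        target_event_fraction = 19 / 214,
                        admin_horizon = 1460,
                        dropout_mean = 365,
                        p_male = 0.67,
                        p_ever_smoker = 0.69,
                        p_ps_2_4 = 5 / 214,
                        p_gene_abnormality = 63 / 214,
                        p_operation = 0.25,
                        p_radiation = 0.30,
                        p_histology = c(adenocarcinoma = 136, squamous = 35,
                                        small_cell = 31, other = 12) / 214,
                        p_stage = c(I = 4, II = 14, III = 53,
                                    IV_recurrence = 143) / 214,
                        p_gs_category = c(none = 93, mild = 77,
                                          moderate = 36, severe = 8) / 214,
                        age_mean = 66, age_sd = 10, age_range = c(25, 85),
                        censor_reason_probs = c(death = 0.7, transfer = 0.1,
                                                lost = 0.1,
                                                ici_initiation = 0.1)) {
  spec <- list(n = n, p_ild = p_ild, hfs_excess_mean = hfs_excess_mean,
               hfs_excess_max = hfs_excess_max, beta_hfs = beta_hfs,
               baseline_hazard = baseline_hazard,
               target_event_fraction = target_event_fraction,
               admin_horizon = admin_horizon, dropout_mean = dropout_mean,
               p_male = p_male, p_ever_smoker = p_ever_smoker,
               p_ps_2_4 = p_ps_2_4, p_gene_abnormality = p_gene_abnormality,
               p_operation = p_operation, p_radiation = p_radiation,
               p_histology = p_histology, p_stage = p_stage,
               p_gs_category = p_gs_category,
               age_mean = age_mean, age_sd = age_sd, age_range = age_range,
               censor_reason_probs = censor_reason_probs)
  probs <- c(p_ild, p_male, p_ever_smoker, p_ps_2_4, p_gene_abnormality,
             p_operation, p_radiation, p_histology, p_stage, p_gs_category,
             censor_reason_probs, target_event_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  for (nm in c("p_histology", "p_stage", "p_gs_category", "censor_reason_probs")) {
    if (abs(sum(spec[[nm]]) - 1) > 1e-8) stop(nm, " must sum to 1")
  }
  if (n < 2) stop("n must be at least 2")
  if (target_event_fraction <= 0 && is.null(baseline_hazard)) {
    stop("cannot calibrate a baseline hazard to a zero event fraction")
  }
  class(spec) <- "cohort_spec"
  if (is.null(spec$baseline_hazard)) {
    spec$baseline_hazard <- calibrate_baseline_hazard(spec)
  }
  spec
}

#' HFS-excess lattice distribution
#'
#' The HFS excess (HFS - 100) of an ILD patient lives on the lattice of
#' multiples of 5/6 points (one 5% extent step in one of six regions). The
#' truncated-exponential excess distribution is discretised onto this
#' lattice by assigning each lattice point the truncated-exponential mass of
#' the half-step interval around it.
#'
#' @param spec A [cohort_spec()].
#' @return Data frame with `k` (lattice index), `excess` (points) and `prob`.
#' @export
hfs_excess_lattice <- function(spec) {
  step <- HFS_LATTICE_STEP
  kmax <- round(spec$hfs_excess_max / step)
  k <- seq_len(kmax)
  rate <- 1 / spec$hfs_excess_mean
  cdf <- function(z) {
    z <- pmin(pmax(z, 0), spec$hfs_excess_max)
    (1 - exp(-rate * z)) / (1 - exp(-rate * spec$hfs_excess_max))
  }
  lower <- c(0, (k[-kmax] + 0.5) * step)
  upper <- c((k[-kmax] + 0.5) * step, spec$hfs_excess_max)
  data.frame(k = k, excess = k * step, prob = cdf(upper) - cdf(lower))
}

# P(event before censoring) for a patient with HFS excess z:
# event time ~ Exp(theta), dropout ~ Exp(mu), horizon H =>
# P = theta / (theta + mu) * (1 - exp(-(theta + mu) H)).
event_probability <- function(lambda, z, spec) {
  theta <- lambda * exp(spec$beta_hfs * z)
  mu <- 1 / spec$dropout_mean
  theta / (theta + mu) * (1 - exp(-(theta + mu) * spec$admin_horizon))
}

#' Calibrate the baseline hazard to a target event fraction
#'
#' Solves, in closed form up to a one-dimensional root search, for the
#' baseline exponential hazard at which the marginal event probability --
#' mixing the closed-form per-patient event probability over the discretised
#' HFS-excess distribution -- equals the spec's target event fraction.
#' Deterministic; no simulation involved.
#'
#' @param spec A [cohort_spec()] (its `baseline_hazard` is ignored).
#' @return Baseline hazard per day.
#' @export
calibrate_baseline_hazard <- function(spec) {
  lat <- hfs_excess_lattice(spec)
  marginal <- function(lambda) {
    (1 - spec$p_ild) * event_probability(lambda, 0, spec) +
      spec$p_ild * sum(lat$prob * event_probability(lambda, lat$excess, spec))
  }
  stats::uniroot(function(l) marginal(l) - spec$target_event_fraction,
                 interval = c(1e-12, 1), tol = 1e-14)$root
}

#' Simulate a synthetic lung-cancer chemotherapy cohort
#'
#' Draws a cohort under the spec: ILD status, an HFS on the reachable
#' lattice, independent covariates at the specified marginals, an event time
#' from an exponential hazard `baseline_hazard * exp(beta_hfs * (hfs - 100))`,
#' censoring from exponential dropout and the administrative horizon, and a
#' censoring reason. Follow-up times are rounded up to whole days.
#' Reproducible: the same `(spec, seed)` yields the identical cohort.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed.
#' @return Cohort data frame with columns `patient_id`, `hfs`, `gs`, `age`,
#'   `sex`, `ecog_ps`, `smoking`, `histology`, `stage`, `gene_abnormality`,
#'   `operation`, `radiation`, `time_days`, `event`, `censor_reason`.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 50), seed = 1)
#' table(cohort$event)
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(seed)
  n <- spec$n

  ild <- stats::rbinom(n, 1, spec$p_ild) == 1
  lat <- hfs_excess_lattice(spec)
  k <- integer(n)
  k[ild] <- sample(lat$k, sum(ild), replace = TRUE, prob = lat$prob)
  hfs <- 100 + k * HFS_LATTICE_STEP

  gs_cat <- sample(names(spec$p_gs_category), n, replace = TRUE,
                   prob = spec$p_gs_category)
  gs <- integer(n)
  gs[gs_cat == "mild"] <- sample(1:7, sum(gs_cat == "mild"), replace = TRUE)
  gs[gs_cat == "moderate"] <- sample(8:15, sum(gs_cat == "moderate"), replace = TRUE)
  gs[gs_cat == "severe"] <- sample(16:24, sum(gs_cat == "severe"), replace = TRUE)

  age <- pmin(pmax(round(stats::rnorm(n, spec$age_mean, spec$age_sd)),
                   spec$age_range[1]), spec$age_range[2])

  theta <- spec$baseline_hazard * exp(spec$beta_hfs * (hfs - 100))
  t_event <- stats::rexp(n, rate = theta)
  dropout <- stats::rexp(n, rate = 1 / spec$dropout_mean)
  t_censor <- pmin(dropout, spec$admin_horizon)
  event <- as.integer(t_event <= t_censor)
  time_days <- ceiling(pmin(t_event, t_censor))

  reason <- rep("none", n)
  cens <- event == 0L
  admin <- cens & dropout >= spec$admin_horizon
  reason[admin] <- "admin_end"
  other <- cens & !admin
  reason[other] <- sample(names(spec$censor_reason_probs), sum(other),
                          replace = TRUE, prob = spec$censor_reason_probs)

  cohort <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)),
    hfs = hfs,
    gs = gs,
    age = age,
    sex = ifelse(stats::rbinom(n, 1, spec$p_male) == 1, "male", "female"),
    ecog_ps = ifelse(stats::rbinom(n, 1, spec$p_ps_2_4) == 1,
                     sample(2:4, n, replace = TRUE), sample(0:1, n, replace = TRUE)),
    smoking = ifelse(stats::rbinom(n, 1, spec$p_ever_smoker) == 1,
                     "ever", "never"),
    histology = sample(names(spec$p_histology), n, replace = TRUE,
                       prob = spec$p_histology),
    stage = sample(names(spec$p_stage), n, replace = TRUE,
                   prob = spec$p_stage),
    gene_abnormality = stats::rbinom(n, 1, spec$p_gene_abnormality),
    operation = stats::rbinom(n, 1, spec$p_operation),
    radiation = stats::rbinom(n, 1, spec$p_radiation),
    time_days = time_days,
    event = event,
    censor_reason = reason,
    stringsAsFactors = FALSE
  )
  attr(cohort, "spec") <- spec
  cohort
}

#' Reader-noise specification
#'
#' Parameters of the two-reader scoring noise. Each reader's six-region
#' fibrosis read deviates from the patient's target HFS by a symmetric
#' lattice perturbation: the magnitude is `m` or `m + 1` lattice steps
#' (randomised so the calibrated noise variance is hit exactly despite the
#' discrete grid), capped at the patient's HFS excess so the 100-point floor
#' is never clipped, with an independent equiprobable sign. Patients without
#' ILD are read as fully normal by every reader. Because no clipping occurs,
#' the population intraclass correlation is exactly
#' `var(targets) / (var(targets) + noise_var)`.
#'
#' @param n_readers Number of readers.
#' @param icc_target Population ICC to calibrate the noise variance to
#'   (used when `noise_sd` is `NULL`).
#' @param noise_sd Noise standard deviation in HFS points; overrides
#'   `icc_target` when given.
#' @param confusion_prob Per-region probability of confusing reticular
#'   abnormality with reticular abnormality plus traction bronchiectasis
#'   (moves one 5% tranche between the two categories; adds variance beyond
#'   the calibrated model, so defaults to 0).
#' @return Object of class `"reader_noise_spec"`.
#' @export
reader_noise_spec <- function(n_readers = 2, icc_target = 0.96,
                              noise_sd = NULL, confusion_prob = 0) {
  if (n_readers < 1) stop("need at least one reader")
  if (is.null(noise_sd) && (icc_target <= 0 || icc_target > 1)) {
    stop("icc_target must lie in (0, 1]")
  }
  structure(list(n_readers = n_readers, icc_target = icc_target,
                 noise_sd = noise_sd, confusion_prob = confusion_prob),
            class = "reader_noise_spec")
}

# Split q = 5 * m points of excess in one region among the weighted
# categories: reticular first, then reticular + traction bronchiectasis,
# then honeycombing. Vectorised over regions.
excess_partition <- function(q) {
  if (any(q < 0 | q > 300)) stop("region excess out of range")
  e2 <- ifelse(q <= 100, q, ifelse(q <= 200, 200 - q, 0))
  e3 <- ifelse(q <= 100, 0, ifelse(q <= 200, q - 100, 300 - q))
  e4 <- ifelse(q <= 200, 0, q - 200)
  cbind(pct_normal = 100 - e2 - e3 - e4, pct_reticular = e2,
        pct_reticular_tb = e3, pct_honeycomb = e4)
}

#' Simulate region-level reader data for a cohort
#'
#' Emits, for each patient and reader, six region-level fibrosis extent
#' partitions (on the 5% grid) and six low-attenuation-area extents, such
#' that scoring them with [reader_scores()] reproduces each reader's noisy
#' HFS exactly and the patient's Goddard score exactly. With the noise
#' disabled (`noise_sd = 0`) every reader reads the target partition and the
#' reader-averaged HFS equals the cohort's target HFS exactly.
#'
#' @param cohort Cohort data frame from [simulate_cohort()] (needs
#'   `patient_id`, `hfs`, `gs`); every `hfs` must lie on the 5/6-point
#'   lattice.
#' @param noise A [reader_noise_spec()].
#' @param seed Integer seed.
#' @return Region-read data frame (schema of [reader_scores()]), with
#'   attributes `population_icc` (exact population ICC of the noise model
#'   relative to this cohort's target variance) and `noise_var` (calibrated
#'   noise variance, points^2).
#' @export
simulate_reads <- function(cohort, noise = reader_noise_spec(), seed = 1) {
  stopifnot(inherits(noise, "reader_noise_spec"))
  set.seed(seed)
  step <- HFS_LATTICE_STEP
  k_target <- (cohort$hfs - 100) / step
  off <- abs(k_target - round(k_target)) > 1e-6
  if (any(off)) {
    stop("target HFS not reachable on the 5/6-point lattice for patient(s): ",
         paste(utils::head(cohort$patient_id[off], 5), collapse = ", "))
  }
  k_target <- as.integer(round(k_target))
  n <- length(k_target)

  # calibrate the noise variance (points^2)
  var_h <- stats::var(cohort$hfs)
  target_var <- if (!is.null(noise$noise_sd)) {
    noise$noise_sd^2
  } else {
    var_h * (1 - noise$icc_target) / noise$icc_target
  }
  # achievable noise variance with magnitude m steps, capped per patient
  cap <- pmin(k_target, 360L - k_target)  # keep reads within [100, 400]
  f <- function(m) mean(pmin(cap, m)^2) * step^2
  if (target_var <= 0 || max(cap) == 0) {
    m <- 0L; q <- 0
  } else if (f(360) <= target_var) {
    warning("requested noise variance not achievable; using maximum")
    m <- 360L; q <- 0
  } else {
    m <- 0L
    while (f(m + 1L) <= target_var) m <- m + 1L
    q <- (target_var - f(m)) / (f(m + 1L) - f(m))
  }
  achieved_var <- (1 - q) * f(m) + q * f(m + 1L)

  n_readers <- noise$n_readers
  reader_ids <- sprintf("R%d", seq_len(n_readers))

  # per patient x reader noisy lattice totals
  magnitude <- matrix(m + (stats::runif(n * n_readers) < q), n, n_readers)
  magnitude <- pmin(magnitude, matrix(cap, n, n_readers))
  sign <- matrix(ifelse(stats::runif(n * n_readers) < 0.5, -1, 1), n, n_readers)
  k_read <- sweep(magnitude * sign, 1, k_target, "+")

  # six-region split of each read: lattice units spread as evenly as possible
  per_pr <- as.vector(k_read)                       # patient fastest, reader outer
  base <- per_pr %/% 6L
  rem <- per_pr %% 6L
  reg_index <- rep(seq_len(6L), times = n * n_readers)
  m_r <- rep(base, each = 6L) + as.integer(reg_index <= rep(rem, each = 6L))
  ext <- excess_partition(5 * m_r)

  # Goddard score split: identical for all readers (regions on the 0-4 scale)
  gs <- as.integer(cohort$gs)
  if (any(gs < 0 | gs > 24)) stop("gs must lie in [0, 24]")
  gs_base <- gs %/% 6L
  gs_rem <- gs %% 6L
  gs_region <- rep(gs_base, each = 6L) +
    as.integer(rep(seq_len(6L), times = n) <= rep(gs_rem, each = 6L))
  laa_map <- c(0, 15, 40, 60, 80)
  laa_one <- laa_map[gs_region + 1L]                # per patient, six regions

  reads <- data.frame(
    patient_id = rep(rep(cohort$patient_id, each = 6L), times = n_readers),
    reader_id = rep(reader_ids, each = 6L * n),
    region_id = rep(region_ids(), times = n * n_readers),
    ext,
    laa_percent = rep(laa_one, times = n_readers),
    stringsAsFactors = FALSE
  )

  if (noise$confusion_prob > 0) {
    can_up <- reads$pct_reticular >= 5
    can_down <- reads$pct_reticular_tb >= 5
    u <- stats::runif(nrow(reads))
    up <- u < noise$confusion_prob / 2 & can_up
    down <- !up & u < noise$confusion_prob & can_down
    reads$pct_reticular[up] <- reads$pct_reticular[up] - 5
    reads$pct_reticular_tb[up] <- reads$pct_reticular_tb[up] + 5
    reads$pct_reticular_tb[down] <- reads$pct_reticular_tb[down] - 5
    reads$pct_reticular[down] <- reads$pct_reticular[down] + 5
  }

  attr(reads, "population_icc") <- if (var_h + achieved_var > 0) {
    var_h / (var_h + achieved_var)
  } else NA_real_
  attr(reads, "noise_var") <- achieved_var
  reads
}
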