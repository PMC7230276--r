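# Prevalence estimates and the 2x2 chi-square comparison.

#' Proportion estimate with confidence interval
#'
#' Point estimate and confidence interval for a binomial proportion, reported
#' on the percent scale. The default Wald (normal-approximation) interval
#' p +/- z * sqrt(p (1 - p) / n) may extend below 0 or above 100 for extreme
#' proportions; the Wilson score interval is available as an alternative.
#'
#' @param x Number of successes (events).
#' @param n Denominator (must be positive, `x <= n`).
#' @param conf_level Confidence level (default 0.95).
#' @param method `"wald"` (default) or `"wilson"`.
#' @return Data frame with columns `numerator`, `denominator`, `percent`,
#'   `ci_low`, `ci_high` (all percentages).
#' @examples
#' proportion_ci(61, 214)
#' @export
proportion_ci <- function(x, n, conf_level = 0.95,
                          method = c("wald", "wilson")) {
  method <- match.arg(method)
  if (any(n <= 0)) stop("denominator must be positive")
  if (any(x < 0 | x > n)) stop("numerator must lie in [0, denominator]")
  p <- x / n
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (method == "wald") {
    half <- z * sqrt(p * (1 - p) / n)
    lo <- p - half
    hi <- p + half
  } else {
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lo <- centre - half
    hi <- centre + half
  }
  data.frame(numerator = x, denominator = n, percent = 100 * p,
             ci_low = 100 * lo, ci_high = 100 * hi)
}

#' Pearson chi-square test on a 2x2 table
#'
#' Tests independence of event status and exposure in a 2x2 table, by default
#' without Yates continuity correction.
#'
#' @param table 2x2 matrix of counts, rows = exposure groups, columns =
#'   event / no event.
#' @param correct Apply the Yates continuity correction.
#' @return List with `statistic`, `df`, `p`.
#' @examples
#' chisq_2x2(matrix(c(15, 4, 46, 149), nrow = 2)) # events by ILD status
#' @export
chisq_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("table must be 2x2")
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("all margins of the 2x2 table must be positive")
  }
  ht <- stats::chisq.test(table, correct = correct)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Prevalence summary for a cohort
#'
#' Computes, from a cohort table (see [read_cohort_csv()] for the schema),
#' the prevalence of pre-existing ILD (HFS > 100), the prevalence of
#' drug-induced pneumonia overall and within patients with and without ILD,
#' and the chi-square comparison of pneumonia incidence by ILD status.
#'
#' @param cohort Cohort data frame with at least `hfs` and `event` columns.
#' @param conf_level,method Passed to [proportion_ci()].
#' @param correct Passed to [chisq_2x2()].
#' @return List with `prevalence` (data frame of the four proportion
#'   estimates, labelled by a `measure` column) and `chisq` (the 2x2 test of
#'   pneumonia by ILD status).
#' @export
prevalence_summary <- function(cohort, conf_level = 0.95, method = "wald",
                               correct = FALSE) {
  stopifnot(all(c("hfs", "event") %in% names(cohort)))
  ild <- cohort$hfs > 100
  ev <- cohort$event > 0
  n <- nrow(cohort)
  rows <- rbind(
    cbind(measure = "ild", proportion_ci(sum(ild), n, conf_level, method)),
    cbind(measure = "pneumonia", proportion_ci(sum(ev), n, conf_level, method)),
    cbind(measure = "pneumonia_ild",
          proportion_ci(sum(ev & ild), sum(ild), conf_level, method)),
    cbind(measure = "pneumonia_no_ild",
          proportion_ci(sum(ev & !ild), sum(!ild), conf_level, method))
  )
  tab <- matrix(c(sum(ev & ild), sum(ev & !ild),
                  sum(!ev & ild), sum(!ev & !ild)), nrow = 2)
  list(prevalence = rows, chisq = chisq_2x2(tab, correct = correct))
}
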