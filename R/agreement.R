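# Inter-observer agreement via intraclass correlation.

#' Ratings matrix from per-reader scores
#'
#' Pivots a per-reader score table (as produced by [reader_scores()]) into a
#' complete subjects x raters matrix for one measure.
#'
#' @param scores Data frame with `patient_id`, `reader_id` and the measure
#'   column.
#' @param measure Which score to pivot, `"hfs"` or `"gs"`.
#' @return Numeric matrix with one row per patient and one column per reader.
#' @export
ratings_matrix <- function(scores, measure = c("hfs", "gs")) {
  measure <- match.arg(measure)
  readers <- sort(unique(scores$reader_id))
  patients <- unique(scores$patient_id)
  m <- matrix(NA_real_, nrow = length(patients), ncol = length(readers),
              dimnames = list(as.character(patients), as.character(readers)))
  m[cbind(match(scores$patient_id, patients),
          match(scores$reader_id, readers))] <- scores[[measure]]
  if (anyNA(m)) stop("incomplete ratings: every patient needs a score from every reader")
  m
}

#' Intraclass correlation coefficient for inter-observer agreement
#'
#' Single-measure ICC from the two-way ANOVA (subjects x raters, no
#' replication) mean squares. The default `"agreement"` model is ICC(2,1):
#' two-way random effects, absolute agreement,
#' (MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE)).
#' The `"consistency"` model is ICC(3,1): (MSR - MSE) / (MSR + (k-1) MSE).
#' A 95% confidence interval is computed by the McGraw-Wong F-based method.
#'
#' @param ratings Numeric n x k matrix, one row per subject, one column per
#'   rater; complete, with n >= 2 subjects and k >= 2 raters.
#' @param model `"agreement"` (ICC(2,1), raters random) or `"consistency"`
#'   (ICC(3,1), raters fixed).
#' @param conf_level Confidence level for the interval.
#' @return Object of class `"icc_fit"`: a list with `estimate`, `model`,
#'   `ci_low`, `ci_high`, `conf_level`, the mean squares `msr`, `msc`, `mse`,
#'   and `n`, `k`.
#' @examples
#' m <- cbind(r1 = c(1, 3, 5, 7), r2 = c(2, 4, 6, 8))
#' icc(m)
#' @export
icc <- function(ratings, model = c("agreement", "consistency"),
                conf_level = 0.95) {
  model <- match.arg(model)
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("ratings matrix must be complete (no NA)")
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need at least 2 subjects and 2 raters")

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  if (msr <= mse) {
    warning("between-subject variance does not exceed residual variance; ICC <= 0")
  }

  alpha <- 1 - conf_level
  if (model == "consistency") {
    est <- (msr - mse) / (msr + (k - 1) * mse)
    f_obs <- msr / mse
    fl <- f_obs / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f_obs * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # McGraw & Wong (1996) interval for ICC(A,1), Satterthwaite df
    a <- (k * est) / (n * (1 - est))
    b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f_l <- stats::qf(1 - alpha / 2, n - 1, v)
    f_u <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f_l * mse) /
      (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f_u * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f_u * msr)
    ci <- c(lo, hi)
  }

  structure(list(estimate = est, model = model,
                 ci_low = ci[1], ci_high = ci[2], conf_level = conf_level,
                 msr = msr, msc = msc, mse = mse, n = n, k = k),
            class = "icc_fit")
}

#' @export
print.icc_fit <- function(x, ...) {
  lab <- if (x$model == "agreement") "ICC(2,1) absolute agreement" else "ICC(3,1) consistency"
  cat(sprintf("%s: %.3f (%d%% CI %.3f-%.3f), n = %d subjects, k = %d raters\n",
              lab, x$estimate, round(100 * x$conf_level),
              x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}
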