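# Fixture builders shared across the suite.

# One reader's six-region fibrosis read from a list of category extents.
# `partitions` is a list of six numeric vectors c(normal, reticular,
# reticular_tb, honeycomb); missing trailing entries default to 0.
make_reads <- function(patient_id, reader_id, partitions, laa = rep(0, 6)) {
  stopifnot(length(partitions) == 6, length(laa) == 6)
  ext <- t(vapply(partitions, function(p) c(p, rep(0, 4 - length(p))),
                  numeric(4)))
  data.frame(patient_id = patient_id, reader_id = reader_id,
             region_id = region_ids(),
             pct_normal = ext[, 1], pct_reticular = ext[, 2],
             pct_reticular_tb = ext[, 3], pct_honeycomb = ext[, 4],
             laa_percent = laa, stringsAsFactors = FALSE)
}

# The two worked-example patients: one reader's regions as printed alongside
# the example images (patient A: one fully normal region, four regions with
# 5% reticulation, one with 10%; patient B: 20/25/25/25/25/30% reticulation),
# plus patient B's emphysema with all six fields in the 51-75% LAA band.
example_reader_A <- function(reader_id = "HG") {
  make_reads("A", reader_id, list(
    c(100), c(95, 5), c(95, 5), c(95, 5), c(95, 5), c(90, 10)
  ))
}

example_reader_B <- function(reader_id = "HG") {
  make_reads("B", reader_id, list(
    c(80, 20), c(75, 25), c(75, 25), c(75, 25), c(75, 25), c(70, 30)
  ), laa = rep(60, 6))
}

# A small survival fixture with distinct event times: 6 subjects, binary
# covariate, events interleaved across the two covariate groups so the
# partial-likelihood maximiser is finite.
six_subject_fixture <- function() {
  list(time = c(2, 4, 6, 8, 10, 12),
       event = c(1, 1, 1, 0, 1, 0),
       x = c(1, 0, 0, 1, 1, 0))
}

# Explicit Cox partial log-likelihood for untied data, coded independently
# of the package (direct risk-set sums).
partial_loglik <- function(beta, time, event, x) {
  sum(vapply(which(event == 1), function(i) {
    at_risk <- time >= time[i]
    x[i] * beta - log(sum(exp(x[at_risk] * beta)))
  }, 0))
}

# Mean squares from stats::aov on a subjects x raters matrix, used as the
# two-way ANOVA oracle for the ICC.
aov_mean_squares <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                  rater = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + rater, data = d))[[1]]
  list(msr = tab["subject", "Mean Sq"],
       msc = tab["rater", "Mean Sq"],
       mse = tab["Residuals", "Mean Sq"])
}
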