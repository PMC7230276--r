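# Risk-factor tables: simple Cox per candidate factor and bivariable
# "replaced multiple" models that re-fit HFS alongside one adjuster at a time.

histology_levels <- function() c("adenocarcinoma", "squamous", "small_cell", "other")
stage_levels <- function() c("I_II", "III", "IV_recurrence")

# Dummy-coded covariate blocks per analysis variable. Reference levels:
# age < 70, female, ECOG-PS 0-1, adenocarcinoma, stage III, never-smoker,
# no gene abnormality, no operation, no radiation.
covariate_block <- function(cohort, variable) {
  switch(variable,
    age = cbind(age_ge70 = as.numeric(cohort$age >= 70)),
    gender = cbind(male = as.numeric(cohort$sex == "male")),
    ecog_ps = cbind(ps_2_4 = as.numeric(cohort$ecog_ps >= 2)),
    histology = {
      h <- factor(cohort$histology, levels = histology_levels())
      cbind(squamous = as.numeric(h == "squamous"),
            small_cell = as.numeric(h == "small_cell"),
            other = as.numeric(h == "other"))
    },
    stage = {
      s <- ifelse(cohort$stage %in% c("I", "II"), "I_II",
                  as.character(cohort$stage))
      cbind(stage_I_II = as.numeric(s == "I_II"),
            stage_IV_recurrence = as.numeric(s == "IV_recurrence"))
    },
    smoking = cbind(ever_smoker = as.numeric(cohort$smoking == "ever")),
    gene_abnormality = cbind(gene_abnormal = as.numeric(cohort$gene_abnormality > 0)),
    gs = cbind(gs = as.numeric(cohort$gs)),
    hfs = cbind(hfs = as.numeric(cohort$hfs - 100)),
    operation = cbind(operation = as.numeric(cohort$operation > 0)),
    radiation = cbind(radiation = as.numeric(cohort$radiation > 0)),
    stop("unknown analysis variable: ", variable)
  )
}

analysis_variables <- function() {
  c("age", "gender", "ecog_ps", "histology", "stage", "smoking",
    "gene_abnormality", "gs", "hfs", "operation", "radiation")
}

# A dummy column with no events on one of its sides has a monotone partial
# likelihood: flagged not-calculable rather than silently dropped.
nc_columns <- function(block, event) {
  binary <- apply(block, 2, function(col) all(col %in% c(0, 1)))
  nc <- logical(ncol(block))
  for (j in which(binary)) {
    nc[j] <- sum(event[block[, j] == 1]) == 0
  }
  colnames(block)[nc]
}

#' Simple Cox analysis of each candidate risk factor
#'
#' Fits one Cox model per analysis variable (age >= 70, male sex, ECOG-PS
#' 2-4, histology, clinical stage, smoking history, gene abnormality, GS per
#' point, HFS per point, prior operation, prior radiation) against the
#' drug-induced pneumonia endpoint, and assembles the hazard ratios with
#' Wald confidence intervals. HFS enters per point, centred at 100 (the
#' hazard ratio per point is unchanged by centring). Factor levels with zero
#' events are reported as not calculable (`note = "n/c"`) and excluded from
#' that variable's fit.
#'
#' @param cohort Cohort data frame (see [read_cohort_csv()] for the schema).
#' @param variables Analysis variables to include; defaults to all.
#' @param ties,conf_level Passed to [cox_fit()].
#' @return Data frame with columns `variable`, `term`, `hr`, `ci_low`,
#'   `ci_high`, `p`, `note` (`"ref"` rows carry hr = 1).
#' @export
cox_table <- function(cohort, variables = analysis_variables(),
                      ties = "breslow", conf_level = 0.95) {
  out <- list()
  for (v in variables) {
    block <- covariate_block(cohort, v)
    nc <- nc_columns(block, cohort$event)
    keep <- setdiff(colnames(block), nc)
    rows <- data.frame(variable = v, term = colnames(block),
                       hr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                       p = NA_real_, note = "", stringsAsFactors = FALSE)
    rows$note[rows$term %in% nc] <- "n/c"
    if (length(keep) > 0) {
      fit <- cox_fit(cohort$time_days, cohort$event,
                     block[, keep, drop = FALSE],
                     ties = ties, conf_level = conf_level)
      m <- match(fit$coefficients$term, rows$term)
      rows$hr[m] <- fit$coefficients$hr
      rows$ci_low[m] <- fit$coefficients$ci_low
      rows$ci_high[m] <- fit$coefficients$ci_high
      rows$p[m] <- fit$coefficients$p
      if (!fit$converged) rows$note[m] <- "not converged"
    }
    out[[v]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Replaced multiple Cox analyses for the HFS effect
#'
#' Robustness check for the per-point HFS effect: one bivariable Cox model
#' per adjuster, each containing HFS (per point, centred at 100) plus one
#' other candidate risk factor, reporting the HFS coefficient from every
#' model alongside the simple (unadjusted) fit.
#'
#' @param cohort Cohort data frame.
#' @param adjusters Variables to adjust by, one model each; defaults to all
#'   analysis variables except HFS itself.
#' @param ties,conf_level Passed to [cox_fit()].
#' @return Data frame with one row per model (`adjuster = "none"` for the
#'   simple fit) and the HFS `hr`, `ci_low`, `ci_high`, `p`.
#' @export
replaced_multiple <- function(cohort,
                              adjusters = setdiff(analysis_variables(), "hfs"),
                              ties = "breslow", conf_level = 0.95) {
  hfs_col <- covariate_block(cohort, "hfs")
  fit_hfs_row <- function(x, label) {
    fit <- cox_fit(cohort$time_days, cohort$event, x,
                   ties = ties, conf_level = conf_level)
    co <- fit$coefficients[fit$coefficients$term == "hfs", ]
    data.frame(adjuster = label, hr = co$hr, ci_low = co$ci_low,
               ci_high = co$ci_high, p = co$p, stringsAsFactors = FALSE)
  }
  out <- list(fit_hfs_row(hfs_col, "none"))
  for (v in adjusters) {
    block <- covariate_block(cohort, v)
    nc <- nc_columns(block, cohort$event)
    block <- block[, setdiff(colnames(block), nc), drop = FALSE]
    x <- cbind(hfs_col, block)
    out[[v]] <- fit_hfs_row(x, v)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Full cohort analysis
#'
#' Runs the complete downstream analysis of a cohort: prevalence estimates
#' with confidence intervals and the chi-square comparison of pneumonia
#' incidence by ILD status, Kaplan-Meier cumulative incidence per HFS
#' stratum, the trend log-rank test across the ordered strata, the simple
#' Cox table over all candidate risk factors, and the replaced-multiple
#' HFS models.
#'
#' @param cohort Cohort data frame (see [read_cohort_csv()]).
#' @param cutoffs HFS stratum cutoffs, default `c(100, 110)`.
#' @param ties Tie handling for all Cox fits.
#' @param conf_level Confidence level throughout.
#' @return Object of class `"cohort_analysis"`: list with `prevalence`,
#'   `chisq`, `km` (named list of [km_fit()] per stratum), `trend`,
#'   `cox_simple`, `cox_replaced`, `strata` (per-patient stratum), and the
#'   settings used.
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 120), seed = 1)
#' ana <- analyze_cohort(cohort)
#' ana$trend$p
#' @export
analyze_cohort <- function(cohort, cutoffs = c(100, 110), ties = "breslow",
                           conf_level = 0.95) {
  prev <- prevalence_summary(cohort, conf_level = conf_level)
  strata <- hfs_stratum(cohort$hfs, cutoffs = cutoffs)
  present <- levels(strata)[levels(strata) %in% unique(as.character(strata))]
  km <- lapply(stats::setNames(present, present), function(s) {
    idx <- strata == s
    km_fit(cohort$time_days[idx], cohort$event[idx])
  })
  trend <- if (length(present) >= 2) {
    logrank_trend(cohort$time_days, cohort$event, strata)
  } else NULL
  structure(list(prevalence = prev$prevalence, chisq = prev$chisq,
                 km = km, trend = trend,
                 cox_simple = cox_table(cohort, ties = ties,
                                        conf_level = conf_level),
                 cox_replaced = replaced_multiple(cohort, ties = ties,
                                                  conf_level = conf_level),
                 strata = strata,
                 settings = list(cutoffs = cutoffs, ties = ties,
                                 conf_level = conf_level)),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat("Cohort analysis\n===============\n")
  cat("\nPrevalence (%, with", paste0(round(100 * x$settings$conf_level), "% CI):\n"))
  pv <- x$prevalence
  pv$percent <- sprintf("%.1f", pv$percent)
  pv$ci <- sprintf("%.1f-%.1f", x$prevalence$ci_low, x$prevalence$ci_high)
  print(pv[, c("measure", "numerator", "denominator", "percent", "ci")],
        row.names = FALSE)
  cat(sprintf("\nPneumonia by ILD status: chi-square = %.2f, p = %s\n",
              x$chisq$statistic, format.pval(x$chisq$p, digits = 3)))
  if (!is.null(x$trend)) {
    cat(sprintf("Trend log-rank across HFS strata: chi-square = %.2f, p = %s\n",
                x$trend$statistic, format.pval(x$trend$p, digits = 3)))
  }
  cat("\nSimple Cox models:\n")
  cs <- x$cox_simple
  cs$hr <- ifelse(cs$note == "n/c", "n/c", sprintf("%.2f", cs$hr))
  cs$ci <- ifelse(cs$note == "n/c", "",
                  sprintf("%.2f-%.2f", x$cox_simple$ci_low, x$cox_simple$ci_high))
  cs$p <- ifelse(cs$note == "n/c", "", format.pval(x$cox_simple$p, digits = 2))
  print(cs[, c("variable", "term", "hr", "ci", "p")], row.names = FALSE)
  cat("\nReplaced multiple Cox models (HFS per point, adjusted one factor at a time):\n")
  cr <- x$cox_replaced
  cr$hr <- sprintf("%.2f", cr$hr)
  cr$ci <- sprintf("%.2f-%.2f", x$cox_replaced$ci_low, x$cox_replaced$ci_high)
  cr$p <- format.pval(x$cox_replaced$p, digits = 2)
  print(cr[, c("adjuster", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}
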