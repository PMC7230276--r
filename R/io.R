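# CSV readers/writers for the two table schemas, and the results writer.

censor_reasons <- function() {
  c("death", "transfer", "lost", "ici_initiation", "admin_end", "none")
}

cohort_columns <- function() {
  c("patient_id", "hfs", "gs", "age", "sex", "ecog_ps", "smoking",
    "histology", "stage", "gene_abnormality", "operation", "radiation",
    "time_days", "event", "censor_reason")
}

check_columns <- function(df, needed, what) {
  missing <- setdiff(needed, names(df))
  if (length(missing) > 0) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
}

#' Read a region-read CSV
#'
#' One row per patient x reader x region, columns `patient_id`, `reader_id`,
#' `region_id`, `pct_normal`, `pct_reticular`, `pct_reticular_tb`,
#' `pct_honeycomb`, `laa_percent`. The table is validated (known regions,
#' six regions per patient x reader, no duplicates).
#'
#' @param path CSV path (UTF-8, header required).
#' @return Validated region-read data frame.
#' @export
read_region_csv <- function(path) {
  reads <- utils::read.csv(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8")
  check_columns(reads, c("patient_id", "reader_id", "region_id", .extent_cols,
                         "laa_percent"), "region-read CSV")
  validate_reads(reads)
  reads
}

#' Write a region-read CSV
#' @param reads Region-read data frame.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_region_csv <- function(reads, path) {
  utils::write.csv(reads, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort CSV
#'
#' One row per patient; see [simulate_cohort()] for the column set. Validates
#' the censoring tokens, the event indicator and follow-up times, and the
#' rule that an event row carries censor reason `none`.
#'
#' @param path CSV path.
#' @return Validated cohort data frame.
#' @export
read_cohort_csv <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE,
                            fileEncoding = "UTF-8")
  check_columns(cohort, cohort_columns(), "cohort CSV")
  bad <- !cohort$censor_reason %in% censor_reasons()
  if (any(bad)) {
    stop("unknown censor_reason in row(s) ",
         paste(utils::head(which(bad), 5), collapse = ", "), ": ",
         paste(utils::head(unique(cohort$censor_reason[bad]), 5), collapse = ", "))
  }
  if (!all(cohort$event %in% c(0, 1))) stop("event must be 0 or 1")
  if (any(cohort$time_days <= 0)) stop("time_days must be positive")
  conflict <- cohort$event == 1 & cohort$censor_reason != "none"
  if (any(conflict)) {
    stop("event rows must have censor_reason 'none'; offending row(s): ",
         paste(utils::head(which(conflict), 5), collapse = ", "))
  }
  cohort
}

#' Write a cohort CSV
#' @param cohort Cohort data frame.
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write patient scores to CSV
#' @param scores Output of [patient_scores()].
#' @param path Destination path.
#' @return Invisibly, `path`.
#' @export
write_scores_csv <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Write analysis results to a directory
#'
#' Serialises a [analyze_cohort()] result: prevalence table, simple and
#' replaced-multiple Cox tables (hazard ratios formatted to two decimals
#' with a "low-high" CI column alongside the raw values), the trend test,
#' per-stratum Kaplan-Meier curves, optionally a cumulative-incidence figure,
#' and a JSON manifest listing every artifact with its MD5 hash and the
#' settings that produced it.
#'
#' @param analysis A `"cohort_analysis"` object.
#' @param dir Output directory (created if needed).
#' @param figures Also render `cuminc.png`.
#' @return Invisibly, the manifest (also written as `manifest.json`).
#' @export
write_results <- function(analysis, dir, figures = FALSE) {
  stopifnot(inherits(analysis, "cohort_analysis"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  fmt_ci <- function(lo, hi) ifelse(is.na(lo), "", sprintf("%.2f-%.2f", lo, hi))

  prev <- analysis$prevalence
  prev$percent_fmt <- sprintf("%.1f", prev$percent)
  prev$ci_fmt <- sprintf("%.1f-%.1f", prev$ci_low, prev$ci_high)
  p1 <- file.path(dir, "prevalence.csv")
  utils::write.csv(prev, p1, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p1)

  cs <- analysis$cox_simple
  cs$hr_fmt <- ifelse(is.na(cs$hr), cs$note, sprintf("%.2f", cs$hr))
  cs$ci_fmt <- fmt_ci(cs$ci_low, cs$ci_high)
  p2 <- file.path(dir, "cox_simple.csv")
  utils::write.csv(cs, p2, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p2)

  cr <- analysis$cox_replaced
  cr$hr_fmt <- sprintf("%.2f", cr$hr)
  cr$ci_fmt <- fmt_ci(cr$ci_low, cr$ci_high)
  p3 <- file.path(dir, "cox_replaced.csv")
  utils::write.csv(cr, p3, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p3)

  km <- do.call(rbind, lapply(names(analysis$km), function(s) {
    cbind(stratum = s, as.data.frame(analysis$km[[s]]))
  }))
  p4 <- file.path(dir, "km.csv")
  utils::write.csv(km, p4, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p4)

  if (!is.null(analysis$trend)) {
    tr <- data.frame(statistic = analysis$trend$statistic,
                     df = analysis$trend$df, p = analysis$trend$p)
    p5 <- file.path(dir, "trend_logrank.csv")
    utils::write.csv(tr, p5, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p5)
  }

  if (figures) {
    p6 <- file.path(dir, "cuminc.png")
    grDevices::png(p6, width = 800, height = 600)
    plot_cuminc(analysis$km)
    grDevices::dev.off()
    paths <- c(paths, p6)
  }

  manifest <- list(
    settings = analysis$settings,
    artifacts = lapply(paths, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
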