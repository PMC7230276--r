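# Region-level HRCT fibrosis scoring and Goddard emphysema scoring.

#' Lung region identifiers
#'
#' The six lung regions scored on HRCT: left and right lung at the level of
#' the carina, at the level of the right inferior pulmonary vein (ipv), and
#' at the axial level midway between the two.
#'
#' @return Character vector of the six region identifiers.
#' @export
region_ids <- function() {
  c("carina_L", "carina_R", "mid_L", "mid_R", "ipv_L", "ipv_R")
}

#' Fibrosis finding categories and their weights
#'
#' Each region's parenchyma is partitioned (in 5% extent increments) among
#' four CT finding categories, weighted by fibrotic severity: normal
#' attenuation (1), reticular abnormality (2), reticular abnormality with
#' traction bronchiectasis (3), honeycombing (4).
#'
#' @return Named integer vector mapping category to weight.
#' @export
fibrosis_weights <- function() {
  c(normal = 1L, reticular = 2L, reticular_tb = 3L, honeycomb = 4L)
}

.extent_cols <- c("pct_normal", "pct_reticular", "pct_reticular_tb", "pct_honeycomb")

# Snap off-grid extents to the 5% grid: ties round away from the normal
# category (normal down, abnormal up), then the normal extent absorbs any
# residual so the partition still sums to 100.
snap_extents <- function(ext) {
  ext <- as.matrix(ext)
  snapped <- ext
  # abnormal categories: ties up
  snapped[, 2:4] <- 5 * floor(ext[, 2:4] / 5 + 0.5)
  # normal: ties down
  snapped[, 1] <- 5 * ceiling(ext[, 1] / 5 - 0.5)
  snapped[, 1] <- snapped[, 1] + (100 - rowSums(snapped))
  if (any(snapped < 0) || any(snapped[, 1] %% 5 != 0)) {
    stop("off-grid extents could not be snapped to a valid 5% partition")
  }
  snapped
}

#' Fibrosis points for lung regions
#'
#' Computes the weighted extent sum for one or more regions: each finding
#' category's extent percentage is multiplied by its weight (1-4) and the
#' products are summed. A fully normal region scores 100; complete
#' honeycombing scores 400.
#'
#' @param pct_normal,pct_reticular,pct_reticular_tb,pct_honeycomb Numeric
#'   vectors of extent percentages per category. Each region's four extents
#'   must be non-negative multiples of 5 summing to exactly 100.
#' @param allow_offgrid If `TRUE`, off-grid extents are rounded to the
#'   nearest 5% (ties away from the normal category, the normal extent
#'   absorbing the residual) instead of rejected.
#' @param region Optional region labels used in validation error messages.
#' @return Numeric vector of region points in \[100, 400\].
#' @examples
#' region_points(95, 5, 0, 0)   # 105
#' region_points(70, 30, 0, 0)  # 130
#' @export
region_points <- function(pct_normal, pct_reticular, pct_reticular_tb,
                          pct_honeycomb, allow_offgrid = FALSE,
                          region = NULL) {
  ext <- cbind(pct_normal, pct_reticular, pct_reticular_tb, pct_honeycomb)
  if (anyNA(ext)) stop("extent percentages must not contain NA")
  if (any(ext < 0)) stop("extent percentages must be >= 0")
  offgrid <- rowSums(ext %% 5 != 0) > 0
  if (any(offgrid)) {
    if (!allow_offgrid) {
      bad <- if (is.null(region)) which(offgrid) else region[offgrid]
      stop("extents not on the 5% grid for region(s): ",
           paste(bad, collapse = ", "),
           " (use allow_offgrid = TRUE to snap)")
    }
    ext[offgrid, ] <- snap_extents(ext[offgrid, , drop = FALSE])
  }
  bad_sum <- abs(rowSums(ext) - 100) > 1e-8
  if (any(bad_sum)) {
    bad <- if (is.null(region)) which(bad_sum) else region[bad_sum]
    stop("extents must sum to 100 for region(s): ", paste(bad, collapse = ", "))
  }
  as.numeric(ext %*% fibrosis_weights())
}

#' Goddard score for a lung region
#'
#' Bands the low-attenuation-area (LAA) extent of a region into the 0-4
#' Goddard score: <=5% scores 0, (5, 25\] scores 1, (25, 50\] scores 2,
#' (50, 75\] scores 3, and >75% scores 4.
#'
#' @param laa_percent Numeric vector of LAA extent percentages in \[0, 100\].
#' @return Integer vector of region scores in 0-4.
#' @examples
#' gs_region_score(60) # 3
#' @export
gs_region_score <- function(laa_percent) {
  if (anyNA(laa_percent) || any(laa_percent < 0 | laa_percent > 100)) {
    stop("laa_percent must lie in [0, 100]")
  }
  as.integer(cut(laa_percent, breaks = c(-Inf, 5, 25, 50, 75, Inf),
                 labels = FALSE)) - 1L
}

validate_reads <- function(reads) {
  needed <- c("patient_id", "reader_id", "region_id", .extent_cols, "laa_percent")
  missing <- setdiff(needed, names(reads))
  if (length(missing) > 0) {
    stop("region-read table is missing column(s): ", paste(missing, collapse = ", "))
  }
  bad_region <- !reads$region_id %in% region_ids()
  if (any(bad_region)) {
    stop("unknown region_id: ",
         paste(unique(reads$region_id[bad_region]), collapse = ", "))
  }
  key <- interaction(reads$patient_id, reads$reader_id, drop = TRUE)
  counts <- table(key)
  if (any(counts != 6L)) {
    stop("each patient x reader must have exactly six regions; offending: ",
         paste(utils::head(names(counts)[counts != 6L], 5), collapse = ", "))
  }
  dup <- tapply(reads$region_id, key, function(r) anyDuplicated(r) > 0)
  if (any(dup)) {
    stop("duplicate region_id within patient x reader: ",
         paste(utils::head(names(dup)[dup], 5), collapse = ", "))
  }
  invisible(reads)
}

#' Per-reader HFS and Goddard scores
#'
#' Reduces a region-read table (one row per patient x reader x region) to one
#' row per patient x reader: the HRCT fibrosis score (HFS) is the mean of the
#' six region fibrosis points, and the Goddard score (GS) is the sum of the
#' six region LAA band scores.
#'
#' @param reads Data frame with columns `patient_id`, `reader_id`,
#'   `region_id`, `pct_normal`, `pct_reticular`, `pct_reticular_tb`,
#'   `pct_honeycomb`, `laa_percent`.
#' @inheritParams region_points
#' @return Data frame with columns `patient_id`, `reader_id`, `hfs`, `gs`.
#' @export
reader_scores <- function(reads, allow_offgrid = FALSE) {
  validate_reads(reads)
  pts <- region_points(reads$pct_normal, reads$pct_reticular,
                       reads$pct_reticular_tb, reads$pct_honeycomb,
                       allow_offgrid = allow_offgrid,
                       region = paste(reads$patient_id, reads$reader_id,
                                      reads$region_id, sep = "/"))
  gsr <- gs_region_score(reads$laa_percent)
  key <- paste(reads$patient_id, reads$reader_id, sep = "\r")
  first <- !duplicated(key)
  out <- data.frame(
    patient_id = reads$patient_id[first],
    reader_id = reads$reader_id[first],
    hfs = as.numeric(tapply(pts, key, mean)[key[first]]),
    gs = as.numeric(tapply(gsr, key, sum)[key[first]]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Patient-level averaged scores with severity categories
#'
#' Averages per-reader HFS and GS across the available readers (one or more)
#' for each patient and attaches the ILD severity category, the emphysema
#' severity category, and the HFS analysis stratum.
#'
#' @param reads Region-read table as in [reader_scores()], or a per-reader
#'   score table already holding columns `patient_id`, `reader_id`, `hfs`,
#'   `gs`.
#' @inheritParams region_points
#' @param cutoffs Stratum cutoffs passed to [hfs_stratum()].
#' @return Data frame with columns `patient_id`, `hfs`, `gs`, `ild_severity`,
#'   `emphysema_severity`, `hfs_stratum`.
#' @examples
#' reads <- example_reads()
#' patient_scores(reads)
#' @export
patient_scores <- function(reads, allow_offgrid = FALSE, cutoffs = c(100, 110)) {
  per_reader <- if (all(c("hfs", "gs") %in% names(reads))) {
    reads
  } else {
    reader_scores(reads, allow_offgrid = allow_offgrid)
  }
  if (nrow(per_reader) == 0) stop("no reader assessments supplied")
  pid <- per_reader$patient_id
  first <- !duplicated(pid)
  hfs <- as.numeric(tapply(per_reader$hfs, pid, mean)[as.character(pid[first])])
  gs <- as.numeric(tapply(per_reader$gs, pid, mean)[as.character(pid[first])])
  out <- data.frame(
    patient_id = pid[first],
    hfs = hfs,
    gs = gs,
    ild_severity = ild_severity(hfs),
    emphysema_severity = emphysema_severity(gs),
    hfs_stratum = hfs_stratum(hfs, cutoffs = cutoffs),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' ILD severity category from the HFS
#'
#' HFS 100 is normal (no ILD); (100, 200\] mild; (200, 300\] moderate;
#' (300, 400\] severe. Half-open bands accommodate non-integer averaged
#' scores (e.g. 122.5 is mild).
#'
#' @param hfs Numeric vector of HFS values in \[100, 400\].
#' @return Factor with levels `none`, `mild`, `moderate`, `severe`.
#' @export
ild_severity <- function(hfs) {
  if (anyNA(hfs) || any(hfs < 100 | hfs > 400)) {
    stop("hfs must lie in [100, 400]")
  }
  cut(hfs, breaks = c(100, 200, 300, 400),
      labels = c("mild", "moderate", "severe"),
      include.lowest = FALSE, right = TRUE) -> band
  f <- factor(ifelse(hfs == 100, "none", as.character(band)),
              levels = c("none", "mild", "moderate", "severe"))
  f
}

#' Emphysema severity category from the Goddard score
#'
#' GS 0 is no emphysema; (0, 7\] mild; (7, 15\] moderate; (15, 24\] severe.
#'
#' @param gs Numeric vector of Goddard scores in \[0, 24\].
#' @return Factor with levels `none`, `mild`, `moderate`, `severe`.
#' @export
emphysema_severity <- function(gs) {
  if (anyNA(gs) || any(gs < 0 | gs > 24)) {
    stop("gs must lie in [0, 24]")
  }
  band <- cut(gs, breaks = c(0, 7, 15, 24),
              labels = c("mild", "moderate", "severe"),
              include.lowest = FALSE, right = TRUE)
  factor(ifelse(gs == 0, "none", as.character(band)),
         levels = c("none", "mild", "moderate", "severe"))
}

#' HFS analysis stratum
#'
#' The cumulative-incidence analysis stratifies patients by HFS exactly 100
#' (no ILD), greater than 100 up to the upper cutoff (default 110), and above
#' the upper cutoff.
#'
#' @param hfs Numeric vector of HFS values in \[100, 400\].
#' @param cutoffs Length-2 numeric vector `c(lower, upper)`; the default
#'   `c(100, 110)` gives strata HFS = 100, 100 < HFS <= 110, HFS > 110.
#' @return Ordered factor with levels `eq100`, `gt100_le110`, `gt110`
#'   (labels follow the cutoffs).
#' @export
hfs_stratum <- function(hfs, cutoffs = c(100, 110)) {
  if (anyNA(hfs) || any(hfs < 100 | hfs > 400)) {
    stop("hfs must lie in [100, 400]")
  }
  stopifnot(length(cutoffs) == 2, cutoffs[1] < cutoffs[2])
  labs <- c(paste0("eq", cutoffs[1]),
            paste0("gt", cutoffs[1], "_le", cutoffs[2]),
            paste0("gt", cutoffs[2]))
  idx <- 1L + (hfs > cutoffs[1]) + (hfs > cutoffs[2])
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Example region-read table
#'
#' A small two-patient, one-reader region-read table illustrating the input
#' schema: patient "A" has subtle reticulation in five regions, patient "B"
#' has more extensive reticulation plus emphysema in the 51-75% LAA band.
#'
#' @return A region-read data frame accepted by [reader_scores()].
#' @export
example_reads <- function() {
  regions <- region_ids()
  rbind(
    data.frame(patient_id = "A", reader_id = "R1", region_id = regions,
               pct_normal = c(100, 95, 95, 95, 95, 90),
               pct_reticular = c(0, 5, 5, 5, 5, 10),
               pct_reticular_tb = 0, pct_honeycomb = 0,
               laa_percent = 0, stringsAsFactors = FALSE),
    data.frame(patient_id = "B", reader_id = "R1", region_id = regions,
               pct_normal = c(80, 75, 75, 75, 75, 70),
               pct_reticular = c(20, 25, 25, 25, 25, 30),
               pct_reticular_tb = 0, pct_honeycomb = 0,
               laa_percent = 60, stringsAsFactors = FALSE)
  )
}
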