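# Kaplan-Meier product-limit estimator.

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function. The complement
#' `1 - surv` is the cumulative incidence reported for drug-induced
#' pneumonia, with death and the other censoring reasons treated as
#' non-informative right censoring.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored).
#' @return Object of class `"km_fit"`: a data frame with one row per distinct
#'   observed time and columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv`, `cuminc`.
#' @examples
#' km_fit(c(1, 2, 3, 4), c(0, 1, 0, 1))
#' @export
km_fit <- function(time, event) {
  if (length(time) == 0) stop("need at least one record")
  if (anyNA(time) || anyNA(event)) stop("time and event must not contain NA")
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(event != 0)
  ut <- sort(unique(time))
  n_event <- as.vector(rowsum(event, time))
  n_total <- as.vector(rowsum(rep(1L, length(time)), time))
  n_censor <- n_total - n_event
  n_risk <- rev(cumsum(rev(n_total)))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censor = n_censor, surv = surv, cuminc = 1 - surv)
  class(out) <- c("km_fit", "data.frame")
  out
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d distinct times, %d events\n",
              nrow(x), sum(x$n_event)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Plot a Kaplan-Meier cumulative-incidence curve
#'
#' Step plot of `1 - S(t)` for one or several fitted curves.
#'
#' @param x A `km_fit`, or a named list of them (one per stratum).
#' @param xlab,ylab,col,... Passed to the underlying plot.
#' @return Invisibly, `x`.
#' @export
plot_cuminc <- function(x, xlab = "Days from first anti-cancer drug",
                        ylab = "Cumulative incidence", col = NULL, ...) {
  curves <- if (inherits(x, "km_fit")) list(x) else x
  if (is.null(col)) col <- seq_along(curves)
  xmax <- max(vapply(curves, function(k) max(k$time), 0))
  ymax <- max(vapply(curves, function(k) max(k$cuminc), 0), 0.05)
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(0, min(1, ymax * 1.1)),
                 xlab = xlab, ylab = ylab, ...)
  for (i in seq_along(curves)) {
    k <- curves[[i]]
    graphics::lines(stats::stepfun(k$time, c(0, k$cuminc)), col = col[i],
                    do.points = FALSE)
  }
  if (!is.null(names(curves))) {
    graphics::legend("topleft", legend = names(curves), col = col, lty = 1,
                     bty = "n")
  }
  invisible(x)
}
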