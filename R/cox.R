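# Cox proportional hazards: Newton-Raphson on the partial likelihood,
# Breslow or Efron handling of tied event times.

# Partial log-likelihood, score vector and observed information at beta,
# on data pre-sorted by increasing time. Suffix sums over the sorted data
# give the risk-set aggregates at each distinct event time.
cox_quantities <- function(beta, tt, dd, X, ties) {
  n <- length(tt)
  p <- ncol(X)
  eta <- drop(X %*% beta)
  w <- exp(eta)

  rcs <- function(v) rev(cumsum(rev(v)))
  s0_full <- rcs(w)
  s1_full <- apply(X * w, 2, rcs)
  s1_full <- matrix(s1_full, nrow = n)
  pair_idx <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  s2_full <- matrix(0, n, nrow(pair_idx))
  for (m in seq_len(nrow(pair_idx))) {
    a <- pair_idx[m, 1]; b <- pair_idx[m, 2]
    s2_full[, m] <- rcs(w * X[, a] * X[, b])
  }

  di <- which(dd == 1L)
  dt <- tt[di]
  ut <- sort(unique(dt))
  fi <- match(ut, tt)            # first at-risk index per distinct event time
  dcount <- as.vector(rowsum(rep(1, length(di)), dt))
  sum_eta_d <- as.vector(rowsum(eta[di], dt))
  sum_x_d <- matrix(rowsum(X[di, , drop = FALSE], dt), ncol = p)

  s0 <- s0_full[fi]
  s1 <- s1_full[fi, , drop = FALSE]
  s2 <- s2_full[fi, , drop = FALSE]

  expand_sym <- function(v) {
    m <- matrix(0, p, p)
    m[cbind(pair_idx[, 1], pair_idx[, 2])] <- v
    m[cbind(pair_idx[, 2], pair_idx[, 1])] <- v
    m
  }

  ll <- sum(sum_eta_d)
  U <- colSums(sum_x_d)
  I <- matrix(0, p, p)

  if (ties == "breslow") {
    ll <- ll - sum(dcount * log(s0))
    xbar <- s1 / s0
    U <- U - colSums(dcount * xbar)
    for (j in seq_along(ut)) {
      v <- expand_sym(s2[j, ]) / s0[j] - tcrossprod(xbar[j, ])
      I <- I + dcount[j] * v
    }
  } else { # efron
    s0_d <- as.vector(rowsum(w[di], dt))
    s1_d <- matrix(rowsum((X * w)[di, , drop = FALSE], dt), ncol = p)
    s2_d <- matrix(0, length(ut), nrow(pair_idx))
    for (m in seq_len(nrow(pair_idx))) {
      a <- pair_idx[m, 1]; b <- pair_idx[m, 2]
      s2_d[, m] <- as.vector(rowsum((w * X[, a] * X[, b])[di], dt))
    }
    for (j in seq_along(ut)) {
      d <- dcount[j]
      for (l in seq_len(d) - 1) {
        frac <- l / d
        phi <- s0[j] - frac * s0_d[j]
        num1 <- s1[j, ] - frac * s1_d[j, ]
        num2 <- expand_sym(s2[j, ] - frac * s2_d[j, ])
        ll <- ll - log(phi)
        U <- U - num1 / phi
        I <- I + num2 / phi - tcrossprod(num1 / phi)
      }
    }
  }
  list(ll = ll, U = U, I = I)
}

#' Cox proportional hazards fit
#'
#' Maximises the Cox partial likelihood by Newton-Raphson with step halving.
#' Tied event times are handled by the Breslow approximation by default, or
#' Efron's. Standard errors come from the inverse observed information;
#' confidence intervals are Wald intervals on the log-hazard scale,
#' exponentiated to the hazard-ratio scale. Convergence is declared when the
#' largest score component falls below `score_tol` or the largest step
#' component below `step_tol`. A monotone partial likelihood (complete
#' separation in the risk sets) drives a coefficient beyond `beta_cap`; the
#' fit then stops with `converged = FALSE` and a warning, the coefficient
#' capped.
#'
#' @param time Positive follow-up times.
#' @param event Event indicator (1 = event, 0 = censored); at least one event.
#' @param x Covariate vector or matrix (one column per covariate); no column
#'   may be constant.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @param init Initial coefficient values (default all 0); the score test is
#'   evaluated here.
#' @param max_iter,score_tol,step_tol,beta_cap Newton-Raphson controls.
#' @param conf_level Confidence level for the Wald intervals.
#' @return Object of class `"cox_fit"`: list with `coefficients` (a data
#'   frame with `beta`, `se`, `hr`, `ci_low`, `ci_high`, `p` per covariate),
#'   `loglik` (at `init` and at the maximum), `score_test` (chi-square
#'   statistic, df, p at `init`), `n`, `n_events`, `iter`, `converged`,
#'   `ties`.
#' @examples
#' fit <- cox_fit(c(2, 4, 6, 8, 10, 12), c(1, 1, 0, 1, 0, 1),
#'                c(1, 1, 1, 0, 0, 0))
#' fit$coefficients
#' @export
cox_fit <- function(time, event, x, ties = c("breslow", "efron"),
                    init = NULL, max_iter = 50, score_tol = 1e-9,
                    step_tol = 1e-10, beta_cap = 15, conf_level = 0.95) {
  ties <- match.arg(ties)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (length(time) != nrow(x) || length(event) != nrow(x)) {
    stop("time, event and x must have matching lengths")
  }
  if (anyNA(time) || anyNA(event) || anyNA(x)) stop("missing values not allowed")
  if (any(time <= 0)) stop("times must be positive")
  event <- as.integer(event != 0)
  if (sum(event) < 1) stop("need at least one event")
  ranges <- apply(x, 2, function(col) diff(range(col)))
  if (any(ranges == 0)) {
    stop("covariate(s) constant across subjects: ",
         paste(colnames(x)[ranges == 0], collapse = ", "))
  }

  p <- ncol(x)
  centers <- colMeans(x)
  xc <- sweep(x, 2, centers)   # centering: identical fit, better conditioning

  ord <- order(time)
  tt <- time[ord]
  dd <- event[ord]
  X <- xc[ord, , drop = FALSE]

  beta <- if (is.null(init)) rep(0, p) else as.numeric(init)
  q <- cox_quantities(beta, tt, dd, X, ties)
  ll0 <- q$ll

  inv_or_stop <- function(I) {
    out <- tryCatch(solve(I), error = function(e) NULL)
    if (is.null(out) || any(!is.finite(out))) {
      stop("singular information matrix: covariates may be collinear")
    }
    out
  }

  score_stat <- drop(t(q$U) %*% inv_or_stop(q$I) %*% q$U)
  score_test <- list(statistic = score_stat, df = p,
                     p = stats::pchisq(score_stat, df = p, lower.tail = FALSE))

  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- drop(inv_or_stop(q$I) %*% q$U)
    # step halving to guarantee ascent
    for (h in 0:20) {
      cand <- beta + step / 2^h
      qn <- cox_quantities(cand, tt, dd, X, ties)
      if (is.finite(qn$ll) && qn$ll >= q$ll - 1e-12) break
    }
    moved <- cand - beta
    beta <- cand
    q <- qn
    if (any(abs(beta) > beta_cap)) {
      warning("monotone partial likelihood: coefficient diverging, capped; ",
              "fit flagged as not converged")
      beta <- pmin(pmax(beta, -beta_cap), beta_cap)
      q <- cox_quantities(beta, tt, dd, X, ties)
      break
    }
    if (max(abs(q$U)) < score_tol || max(abs(moved)) < step_tol) {
      converged <- TRUE
      break
    }
  }
  if (iter == max_iter && max(abs(q$U)) < 1e-5) converged <- TRUE

  vcov <- inv_or_stop(q$I)
  se <- sqrt(diag(vcov))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- data.frame(
    term = colnames(x),
    beta = beta,
    se = se,
    hr = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p = 2 * stats::pnorm(-abs(beta / se)),
    row.names = NULL
  )

  structure(list(coefficients = coefs, vcov = vcov,
                 loglik = c(init = ll0, final = q$ll),
                 score_test = score_test,
                 n = length(tt), n_events = sum(dd),
                 iter = iter, converged = converged, ties = ties,
                 conf_level = conf_level),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional hazards fit (%s ties): n = %d, events = %d%s\n",
              x$ties, x$n, x$n_events,
              if (x$converged) "" else " [NOT CONVERGED]"))
  co <- x$coefficients
  co$hr <- sprintf("%.2f", co$hr)
  co$ci <- sprintf("%.2f-%.2f", x$coefficients$ci_low, x$coefficients$ci_high)
  co$p <- format.pval(x$coefficients$p, digits = 3)
  print(co[, c("term", "hr", "ci", "p")], row.names = FALSE)
  invisible(x)
}
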