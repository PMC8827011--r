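# Univariable Cox proportional-hazards fitting.
#
# The partial likelihood is maximized by Newton iteration with
# step-halving; tied event times use the Efron correction (which changes
# the estimate under ties and is therefore stated, not assumed). For a
# scalar coefficient the score and observed information are scalars, so
# the whole evaluation is vectorized over event times.

# Precompute the tie structure once per dataset.
cox_prepare <- function(x, time, event) {
  ord <- order(time)
  t <- time[ord]; xs <- x[ord]; d <- as.logical(event[ord])
  ut <- unique(t)
  first <- match(ut, t)                    # first index with time >= ut[j]
  death_time <- t[d]
  grp <- match(death_time, ut)             # death-time group per death
  dgrp <- sort(unique(grp))
  dj <- as.integer(table(factor(grp, levels = dgrp)))
  # Efron inner weights l/d for l = 0..d-1, flattened over death times
  l_over_d <- unlist(lapply(dj, function(d1) (seq_len(d1) - 1) / d1))
  rep_j <- rep(seq_along(dgrp), dj)
  list(t = t, xs = xs, d = d, first = first, grp = grp, dgrp = dgrp,
       dj = dj, l_over_d = l_over_d, rep_j = rep_j,
       sum_xd = sum(xs[d]), n_event = sum(d))
}

# Efron log partial likelihood, score and observed information at beta.
cox_eval <- function(beta, pr) {
  r <- exp(beta * pr$xs)
  xr <- pr$xs * r
  x2r <- pr$xs^2 * r
  S0 <- rev(cumsum(rev(r)))
  S1 <- rev(cumsum(rev(xr)))
  S2 <- rev(cumsum(rev(x2r)))
  at <- pr$first[pr$dgrp]                  # risk-set anchor per death time
  S0R <- S0[at]; S1R <- S1[at]; S2R <- S2[at]
  gfac <- factor(pr$grp, levels = pr$dgrp)
  S0D <- as.numeric(tapply(r[pr$d], gfac, sum))
  S1D <- as.numeric(tapply(xr[pr$d], gfac, sum))
  S2D <- as.numeric(tapply(x2r[pr$d], gfac, sum))
  j <- pr$rep_j; l <- pr$l_over_d
  phi0 <- S0R[j] - l * S0D[j]
  phi1 <- S1R[j] - l * S1D[j]
  phi2 <- S2R[j] - l * S2D[j]
  list(loglik = beta * pr$sum_xd - sum(log(phi0)),
       grad = pr$sum_xd - sum(phi1 / phi0),
       info = sum(phi2 / phi0 - (phi1 / phi0)^2))
}

#' Fit a univariable Cox proportional-hazards model
#'
#' Maximizes the Cox partial likelihood for a single continuous or
#' binary covariate by Newton iteration with step-halving, using the
#' Efron correction for tied event times. The hazard ratio is
#' `exp(beta)`, its 95% confidence interval `exp(beta +/- 1.96 * se)`
#' with the standard error from the observed information, and the
#' p-value a two-sided Wald test. The fit is invariant to location
#' shifts of the covariate.
#'
#' A constant covariate, or fewer than two events, is a degenerate-fit
#' error. Non-convergence within `max_iter` iterations or a drifting
#' estimate (`|beta| > 20`, the signature of a monotone likelihood) is
#' flagged on the returned result (`converged = FALSE`, with a warning),
#' never returned silently.
#'
#' @param x Covariate values, one per subject.
#' @param time Follow-up times (any positive scale).
#' @param event Logical (or 0/1) event indicator.
#' @param max_iter Newton iteration cap.
#' @param tol Convergence tolerance on the Newton step.
#' @return A list of class `cox_fit`: `beta`, `se`, `hazard_ratio`,
#'   `ci_low`, `ci_high`, `p_value`, `n_used`, `n_events`, `loglik`,
#'   `iterations`, `converged`.
#' @examples
#' fit <- fit_univariable_cox(c(1, 0, 1, 0), time = c(1, 2, 3, 4),
#'                            event = c(TRUE, TRUE, TRUE, TRUE))
#' fit$hazard_ratio
#' @export
fit_univariable_cox <- function(x, time, event, max_iter = 50L, tol = 1e-9) {
  if (length(x) != length(time) || length(x) != length(event)) {
    stop_labharbor("x, time and event must have equal length",
                   "labharbor_argument_error")
  }
  keep <- stats::complete.cases(x, time, event)
  x <- as.numeric(x[keep]); time <- as.numeric(time[keep])
  event <- as.logical(event[keep])
  if (sum(event) < 2) {
    stop_labharbor("need at least 2 events to fit",
                   "labharbor_degenerate_fit")
  }
  if (length(unique(x)) < 2) {
    stop_labharbor("covariate is constant: degenerate fit",
                   "labharbor_degenerate_fit")
  }
  xc <- x - mean(x)                        # location invariance, numerics
  pr <- cox_prepare(xc, time, event)
  beta <- 0
  e <- cox_eval(beta, pr)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (!is.finite(e$info) || e$info <= 0) break
    step <- e$grad / e$info
    new_beta <- beta + step
    e_new <- cox_eval(new_beta, pr)
    halv <- 0L
    while ((!is.finite(e_new$loglik) || e_new$loglik < e$loglik - 1e-12) &&
           halv < 30L) {
      step <- step / 2
      new_beta <- beta + step
      e_new <- cox_eval(new_beta, pr)
      halv <- halv + 1L
    }
    beta <- new_beta
    e <- e_new
    if (abs(step) < tol) {
      converged <- TRUE
      break
    }
  }
  if (abs(beta) > 20) converged <- FALSE
  if (!converged) {
    warning("Cox fit did not converge (possible monotone likelihood); ",
            "result flagged", call. = FALSE)
  }
  se <- if (is.finite(e$info) && e$info > 0) 1 / sqrt(e$info) else NA_real_
  z <- beta / se
  structure(list(
    beta = beta, se = se,
    hazard_ratio = exp(beta),
    ci_low = exp(beta - 1.96 * se),
    ci_high = exp(beta + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(z)),
    n_used = length(x), n_events = sum(event),
    loglik = e$loglik, iterations = iter, converged = converged),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Univariable Cox fit: HR %.4f (95%% CI %.4g-%.4g), p = %.3g, n = %d (%d events)%s\n",
              x$hazard_ratio, x$ci_low, x$ci_high, x$p_value, x$n_used,
              x$n_events, if (x$converged) "" else " [NOT CONVERGED]"))
  invisible(x)
}
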