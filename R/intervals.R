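#' Wald confidence intervals and tests
#'
#' Symmetric intervals `estimate +/- z * se` on the log hazard-ratio scale,
#' with two-sided normal p-values for each coefficient being zero.
#' Undefined (all-`NA`) for non-converged fits.
#'
#' @param fit A [cox_fit()] object.
#' @param level Confidence level.
#' @return A tibble: `term`, `estimate`, `std.error`, `wald_lo`, `wald_hi`,
#'   `wald_p`.
#' @export
wald_ci <- function(fit, level = 0.95) {
  se <- sqrt(diag(fit$vcov))
  q <- qnorm(1 - (1 - level) / 2)
  est <- unname(fit$coefficients)
  se <- unname(se)
  out <- tibble::tibble(
    term = names(fit$coefficients),
    estimate = est,
    std.error = se,
    wald_lo = est - q * se,
    wald_hi = est + q * se,
    wald_p = 2 * pnorm(-abs(est / se))
  )
  if (!fit$converged) out[, -1] <- NA_real_
  out
}

#' Profile-likelihood deviance of one coefficient
#'
#' `D(b) = 2 * (obj(beta_hat) - obj_profile(b))`, where `obj_profile(b)`
#' maximizes the fit's objective (penalized for Firth fits) over the other
#' coefficients with the chosen coefficient pinned at `b`.  The
#' profile-likelihood confidence set at level `1 - alpha` is
#' `{b : D(b) <= qchisq(1 - alpha, 1)}`, and `D(0)` is the likelihood-ratio
#' statistic of the zero-coefficient test.  Tiny negative values arising
#' from finite solver tolerance are clamped to zero.
#'
#' @param fit A converged [cox_fit()].
#' @param term Coefficient name.
#' @param value Value(s) `b` at which to profile.
#' @return A tibble: `value`, `deviance`, `converged` (inner profile fit).
#' @export
profile_deviance <- function(fit, term, value) {
  purrr::map_dfr(value, function(b) {
    pf <- profile_fit(fit, term, b)
    tibble::tibble(
      value = b,
      deviance = max(0, 2 * (fit$objective - pf$objective)),
      converged = pf$converged && !pf$singular
    )
  })
}

#' Likelihood-ratio test of a zero coefficient
#'
#' For Firth fits the penalized likelihood ratio is used.  The p-value
#' refers `D(0)` to a chi-squared distribution with one degree of freedom.
#'
#' @param fit A converged [cox_fit()].
#' @param term Coefficient name.
#' @return A tibble: `term`, `statistic`, `lr_p`, `converged`.
#' @export
lr_test <- function(fit, term) {
  pd <- profile_deviance(fit, term, 0)
  tibble::tibble(term = term, statistic = pd$deviance,
                 lr_p = pchisq(pd$deviance, df = 1, lower.tail = FALSE),
                 converged = pd$converged)
}

#' Profile-likelihood confidence interval
#'
#' Bounds are the two roots of `D(b) = qchisq(level, 1)` located by outward
#' bracketing from the estimate (doubling steps of one Wald standard error)
#' followed by [uniroot()] to a tolerance of 1e-6 on `b`.  A bound whose
#' bracket is not found within `max_range` log hazard-ratio units of the
#' estimate, or whose inner profile fits fail, is flagged non-converged.
#'
#' @param fit A converged [cox_fit()].
#' @param term Coefficient name (default: all coefficients).
#' @param level Confidence level.
#' @param max_range Search radius on the log hazard-ratio scale.
#' @return A tibble per term: `estimate`, `pl_lo`, `pl_hi`,
#'   `pl_lo_converged`, `pl_hi_converged`, `lr_p`.
#' @export
profile_ci <- function(fit, term = names(fit$coefficients), level = 0.95,
                       max_range = 50) {
  stopifnot(fit$converged)
  crit <- qchisq(level, df = 1)
  purrr::map_dfr(term, function(tm) {
    est <- fit$coefficients[[tm]]
    se <- sqrt(fit$vcov[tm, tm])
    step <- if (is.finite(se) && se > 0) se else 0.5
    bound <- function(dir) {
      delta <- step
      lo_b <- est
      repeat {
        b <- est + dir * delta
        if (abs(b - est) > max_range) return(list(b = NA_real_, ok = FALSE))
        pd <- profile_deviance(fit, tm, b)
        if (!pd$converged) return(list(b = NA_real_, ok = FALSE))
        if (pd$deviance >= crit) break
        lo_b <- b
        delta <- 2 * delta
      }
      root <- uniroot(
        function(bb) profile_deviance(fit, tm, bb)$deviance - crit,
        lower = min(lo_b, b), upper = max(lo_b, b), tol = 1e-6
      )
      list(b = root$root, ok = TRUE)
    }
    lo <- bound(-1)
    hi <- bound(+1)
    tibble::tibble(
      term = tm, estimate = unname(est),
      pl_lo = lo$b, pl_hi = hi$b,
      pl_lo_converged = lo$ok, pl_hi_converged = hi$ok,
      lr_p = lr_test(fit, tm)$lr_p
    )
  })
}

#' Fit both interaction parametrizations of one dataset
#'
#' Fits the interaction model (for inference on the interaction
#' coefficient `MT`) and the subgroup model (for the treatment effects
#' `TM_low`, `TM_high` by marker level) with the same method and solver
#' settings.  For the standard partial likelihood the two fits are exact
#' reparametrizations (`beta_TM_high - beta_TM_low = beta_MT`, equal
#' maximized likelihoods); the Firth penalty is not invariant to
#' reparametrization, so penalized fits may differ slightly and each fit
#' carries its own convergence status.
#'
#' @param data A dataset with columns `M`, `T`, `time`, `event`.
#' @param method `"mple"` or `"firth"`.
#' @param control Solver settings.
#' @param level Confidence level for the intervals.
#' @param profile Also compute profile-likelihood intervals (slower)?
#' @return A list of class `interaction_fits` with elements `interaction`,
#'   `subgroup` (both `cox_fit`) and `intervals`, a tibble of Wald (and
#'   optionally profile-likelihood) intervals for all six coefficients with
#'   a `model` column.
#' @export
fit_both <- function(data, method = c("mple", "firth"),
                     control = cox_control(), level = 0.95, profile = TRUE) {
  method <- match.arg(method)
  fits <- list(
    interaction = cox_fit(data, "interaction", method, control),
    subgroup = cox_fit(data, "subgroup", method, control)
  )
  intervals <- purrr::imap_dfr(fits, function(f, nm) {
    w <- wald_ci(f, level)
    w$model <- nm
    if (profile && f$converged) {
      p <- profile_ci(f, level = level)
      w <- dplyr::left_join(w, p[, c("term", "pl_lo", "pl_hi",
                                     "pl_lo_converged", "pl_hi_converged",
                                     "lr_p")], by = "term")
    }
    w
  })
  structure(list(interaction = fits$interaction, subgroup = fits$subgroup,
                 intervals = intervals, method = method),
            class = "interaction_fits")
}

#' @export
print.interaction_fits <- function(x, ...) {
  cat(sprintf("Marker-treatment interaction analysis (%s)\n",
              ifelse(x$method == "firth", "Firth-penalized Cox",
                     "standard Cox")))
  print(x$intervals, ...)
  invisible(x)
}

#' @rdname tidy.cox_fit
#' @export
tidy.interaction_fits <- function(x, ...) x$intervals
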