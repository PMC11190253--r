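#' Solver settings for Cox model fitting
#'
#' Newton-Raphson from `beta = 0` with every coordinate of each Newton
#' increment clipped to `[-maxstep, maxstep]`.  A fit is converged when the
#' maximum absolute component of the (modified) score drops below `tol`
#' within `maxiter` steps; under a monotone likelihood the walk is cut off
#' by the step bound and the fit is flagged non-converged.
#'
#' @param maxiter Maximum number of Newton steps.
#' @param maxstep Per-coordinate bound on each Newton increment, on the
#'   log hazard-ratio scale.
#' @param tol Convergence tolerance on the score.
#' @return A list of class `cox_control`.
#' @export
cox_control <- function(maxiter = 1000L, maxstep = 0.01, tol = 1e-6) {
  stopifnot(maxiter >= 1, maxstep > 0, tol > 0)
  structure(list(maxiter = as.integer(maxiter), maxstep = maxstep, tol = tol),
            class = "cox_control")
}

#' Design matrix of the two interaction parametrizations
#'
#' `interaction`: columns `(M, T, MT)` with `MT = M * T`, so the third
#' coefficient is the log interaction hazard ratio.  `subgroup`: columns
#' `(M, TM_low, TM_high)` with `TM_low = 1` iff `(M = 0, T = 1)` and
#' `TM_high = 1` iff `(M = 1, T = 1)`; the last two coefficients are the
#' log treatment hazard ratios within each marker level.  The two models
#' span the same space: `beta_TM_high - beta_TM_low = beta_I`.
#'
#' @param data A dataset with columns `M` and `T`.
#' @param parametrization `"interaction"` or `"subgroup"`.
#' @return A numeric matrix with named columns.
#' @export
design_matrix <- function(data, parametrization = c("interaction", "subgroup")) {
  parametrization <- match.arg(parametrization)
  M <- data$M
  Tr <- data$T
  if (parametrization == "interaction") {
    cbind(M = M, T = Tr, MT = M * Tr)
  } else {
    cbind(M = M, TM_low = (1 - M) * Tr, TM_high = M * Tr)
  }
}

#' Cox partial log-likelihood, score and information
#'
#' Evaluates the Breslow partial log-likelihood at `beta`, with its gradient
#' and the observed information (sum over events of the risk-set-weighted
#' covariate covariance).  With `firth = TRUE` also returns the penalized
#' objective `l(beta) + 0.5 * log det I(beta)` and the Firth-modified score
#' `U_j + 0.5 * trace(I^{-1} dI/dbeta_j)`, with the information derivative
#' computed from analytic third-moment risk-set sums.
#'
#' @param data A dataset with columns `M`, `T`, `time`, `event`.
#' @param beta Coefficient vector, one entry per design column.
#' @param parametrization Passed to [design_matrix()].
#' @param firth Evaluate the penalized objective as well?
#' @return A list with `loglik`, `objective`, `score`, `grad_objective`,
#'   `info`, `ok` (information nonsingular and finite).
#' @export
cox_loglik <- function(data, beta, parametrization = "interaction",
                       firth = FALSE) {
  X <- design_matrix(data, parametrization)
  if (sum(data$event) == 0) stop("dataset has no events")
  out <- cox_eval_cpp(X, as.numeric(data$time), as.integer(data$event),
                      as.numeric(beta), firth)
  out$score <- drop(out$score)
  out$grad_objective <- drop(out$grad_objective)
  dimnames(out$info) <- list(colnames(X), colnames(X))
  out
}

cox_newton <- function(X, time, event, method, fixed = NULL,
                       control = cox_control()) {
  p <- ncol(X)
  beta0 <- numeric(p)
  free <- rep(1L, p)
  if (!is.null(fixed)) {
    j <- match(names(fixed), colnames(X))
    if (anyNA(j)) stop("unknown fixed coefficient")
    beta0[j] <- as.numeric(fixed)
    free[j] <- 0L
  }
  res <- cox_newton_cpp(X, as.numeric(time), as.integer(event), beta0,
                        free, identical(method, "firth"),
                        control$maxiter, control$maxstep, control$tol)
  res$coefficients <- setNames(drop(res$coefficients), colnames(X))
  res$score <- setNames(drop(res$score), colnames(X))
  dimnames(res$vcov) <- dimnames(res$info) <- list(colnames(X), colnames(X))
  res
}

#' Fit a Cox interaction model by penalized or plain partial likelihood
#'
#' From-scratch Newton-Raphson maximization of the Breslow partial
#' likelihood (`method = "mple"`) or of the Firth-penalized partial
#' likelihood (`method = "firth"`), which adds `0.5 * log det I(beta)` to
#' the objective, removes the leading small-sample bias and keeps estimates
#' finite under monotone likelihood (e.g. an empty marker-treatment event
#' cell).  Standard errors come from the inverse observed information at
#' the optimum.
#'
#' @param data A dataset with columns `M`, `T`, `time`, `event`.
#' @param parametrization `"interaction"` (coefficients `M`, `T`, `MT`) or
#'   `"subgroup"` (`M`, `TM_low`, `TM_high`); see [design_matrix()].
#' @param method `"mple"` (standard maximum partial likelihood) or
#'   `"firth"`.
#' @param control Solver settings, see [cox_control()].
#' @return An object of class `cox_fit`: a list with `coefficients`,
#'   `vcov`, `loglik` (unpenalized), `objective` (penalized when Firth),
#'   `converged`, `iterations`, `score`, `method`, `parametrization`,
#'   `control`, `n`, `n_events`, and the `data` used.
#' @examples
#' s <- scenario(n = 300, HR_M = 3, HR_I = 0.25)
#' d <- simulate_dataset(s, 1)
#' fit <- cox_fit(d, method = "firth")
#' tidy(fit)
#' @export
cox_fit <- function(data, parametrization = c("interaction", "subgroup"),
                    method = c("mple", "firth"), control = cox_control()) {
  parametrization <- match.arg(parametrization)
  method <- match.arg(method)
  if (sum(data$event) == 0) stop("dataset has no events")
  X <- design_matrix(data, parametrization)
  res <- cox_newton(X, data$time, data$event, method, control = control)
  structure(
    list(coefficients = res$coefficients, vcov = res$vcov,
         loglik = res$loglik, objective = res$objective,
         converged = res$converged && !res$singular,
         singular = res$singular, iterations = res$iterations,
         score = res$score, method = method,
         parametrization = parametrization, control = control,
         n = nrow(data), n_events = sum(data$event), data = data),
    class = "cox_fit")
}

# profile objective: maximize over the other coefficients with one
# coefficient pinned; returns the reduced fit
profile_fit <- function(fit, term, value) {
  X <- design_matrix(fit$data, fit$parametrization)
  cox_newton(X, fit$data$time, fit$data$event, fit$method,
             fixed = setNames(value, term), control = fit$control)
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox %s fit (%s parametrization): n = %d, events = %d\n",
              ifelse(x$method == "firth", "Firth-penalized", "partial-likelihood"),
              x$parametrization, x$n, x$n_events))
  cat(sprintf("converged: %s (%d iterations)\n", x$converged, x$iterations))
  print(tidy(x), ...)
  invisible(x)
}

#' Tidy a Cox fit
#'
#' @param x A `cox_fit`.
#' @param conf.int Add Wald confidence bounds?
#' @param conf.level Confidence level.
#' @param ... Unused.
#' @return A tibble with one row per coefficient: `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value` (Wald), and optionally
#'   `conf.low`/`conf.high`.
#' @export
tidy.cox_fit <- function(x, conf.int = FALSE, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  z <- x$coefficients / se
  out <- tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(z),
    p.value = 2 * pnorm(-abs(unname(z)))
  )
  if (conf.int) {
    q <- qnorm(1 - (1 - conf.level) / 2)
    out$conf.low <- out$estimate - q * out$std.error
    out$conf.high <- out$estimate + q * out$std.error
  }
  out
}

#' One-row summary of a Cox fit
#'
#' @param x A `cox_fit`.
#' @param ... Unused.
#' @return A tibble with `n`, `n_events`, `loglik`, `objective`,
#'   `converged`, `iterations`, `method`, `parametrization`.
#' @export
glance.cox_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_events = x$n_events, loglik = x$loglik,
    objective = x$objective, converged = x$converged,
    iterations = x$iterations, method = x$method,
    parametrization = x$parametrization
  )
}
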