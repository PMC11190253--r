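#' Monte-Carlo performance measures
#'
#' Scalar summaries of per-replicate estimates against a known truth, as
#' used in simulation studies of estimator performance: bias
#' `mean(est) - truth`, relative bias `100 * mean((est - truth) / |truth|)`
#' (undefined at `truth = 0`), the model vs. empirical standard-error
#' comparison `100 * (ModSE / EmpSE - 1)` with `ModSE = sqrt(mean(var))`
#' and `EmpSE = sd(est)` (divisor `N - 1`), interval coverage (closed
#' intervals), and the rejection rate `100 * mean(p <= alpha)` — type I
#' error when the true coefficient is zero, power otherwise.  Boundary
#' p-values equal to `alpha` count as rejections.
#'
#' @param estimates Numeric vector of per-replicate estimates.
#' @param truth True parameter value.
#' @name performance-measures
NULL

#' @rdname performance-measures
#' @export
mc_bias <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  mean(estimates) - truth
}

#' @rdname performance-measures
#' @export
mc_relative_bias <- function(estimates, truth) {
  stopifnot(length(estimates) >= 1)
  if (truth == 0) stop("relative bias is undefined when the truth is 0")
  100 * mean((estimates - truth) / abs(truth))
}

#' @rdname performance-measures
#' @param variances Per-replicate variance estimates (model-based).
#' @export
mc_rel_se_error <- function(variances, estimates) {
  stopifnot(length(estimates) >= 2, length(variances) == length(estimates),
            all(variances >= 0))
  empse <- sd(estimates)
  if (empse == 0) stop("empirical SE is zero")
  100 * (sqrt(mean(variances)) / empse - 1)
}

#' @rdname performance-measures
#' @param lo,hi Interval bounds, one pair per replicate.
#' @export
mc_coverage <- function(lo, hi, truth) {
  stopifnot(length(lo) == length(hi), length(lo) >= 1)
  100 * mean(lo <= truth & truth <= hi)
}

#' @rdname performance-measures
#' @param p_values Per-replicate p-values.
#' @param alpha Significance level in (0, 1).
#' @export
mc_rejection_rate <- function(p_values, alpha = 0.05) {
  stopifnot(length(p_values) >= 1, alpha > 0, alpha < 1)
  100 * mean(p_values <= alpha)
}

# binomial Monte-Carlo SE (percentage points) of a rate given in percent
rate_mcse <- function(pct, n) {
  p <- pct / 100
  100 * sqrt(pmax(p * (1 - p), 0) / n)
}

# jackknife Monte-Carlo SE of the relative SE error (percent)
rel_se_error_mcse <- function(variances, estimates) {
  n <- length(estimates)
  if (n < 3) return(NA_real_)
  sum_v <- sum(variances)
  sum_e <- sum(estimates)
  sum_e2 <- sum(estimates^2)
  loo_modse <- sqrt((sum_v - variances) / (n - 1))
  loo_mean <- (sum_e - estimates) / (n - 1)
  loo_ss <- sum_e2 - estimates^2 - (n - 1) * loo_mean^2
  loo_empse <- sqrt(pmax(loo_ss, 0) / (n - 2))
  theta <- 100 * (loo_modse / loo_empse - 1)
  sqrt((n - 1) / n * sum((theta - mean(theta))^2))
}

#' Summarize per-replicate fit results into scenario performance measures
#'
#' Aggregates the output of [run_scenario()]'s replicate table into one row
#' per (method, coefficient), computing bias, relative bias, model and
#' empirical SE, SE error, Wald and profile-likelihood coverage, and
#' rejection rates, with binomial / jackknife Monte-Carlo standard errors.
#'
#' Two modes: `converged_only` uses only eligible replicates whose fit
#' converged (denominator `N_c`; profile-likelihood measures additionally
#' require the inner profile fit at the evaluated point to converge);
#' `sensitivity` keeps all eligible replicates, counting non-converged fits
#' as covering the truth and not rejecting the null.  Ineligible datasets
#' (more than one empty marker-treatment event cell) are excluded from all
#' denominators in both modes.
#'
#' @param replicates Per-replicate tibble from [run_scenario()].
#' @param scenario The generating one-row scenario tibble.
#' @param mode `"converged_only"` or `"sensitivity"`.
#' @param alpha Significance level for rejection rates.
#' @param level Confidence level of the intervals.
#' @return A tibble, one row per (method, term); percentages in percent.
#'   When the true coefficient is zero the `relative_bias_pct` column is
#'   `NA` (absolute `bias` is the reported measure) and rejection rates are
#'   type I error rates.
#' @export
summarize_replicates <- function(replicates, scenario,
                                 mode = c("converged_only", "sensitivity"),
                                 alpha = 0.05, level = 0.95) {
  mode <- match.arg(mode)
  s <- scenario_coefs(scenario)
  truths <- c(MT = s$beta_I, TM_low = s$beta_TM_low, TM_high = s$beta_TM_high)
  crit <- qchisq(level, df = 1)
  zq <- qnorm(1 - (1 - level) / 2)
  n_generated <- length(unique(replicates$replicate))

  elig <- dplyr::filter(replicates, .data$eligible)
  grid <- tidyr::expand_grid(method = unique(replicates$method),
                             term = names(truths))

  purrr::pmap_dfr(grid, function(method, term) {
    truth <- truths[[term]]
    r <- elig[elig$method == method, , drop = FALSE]
    n_eligible <- nrow(r)
    conv_col <- if (term == "MT") "conv_int" else "conv_sub"
    est <- r[[paste0("est_", term)]]
    v <- r[[paste0("var_", term)]]
    dev_true <- r[[paste0("dev_true_", term)]]
    dev_null <- r[[paste0("dev_null_", term)]]
    ok_true <- r[[paste0("ok_true_", term)]]
    ok_null <- r[[paste0("ok_null_", term)]]
    conv <- r[[conv_col]]

    rc <- dplyr::filter(
      tibble::tibble(est, v, dev_true, dev_null, ok_true, ok_null, conv),
      conv
    )
    n_c <- nrow(rc)
    if (n_c == 0) {
      return(tibble::tibble(
        method = method, term = term, truth = truth, mode = mode,
        n_generated = n_generated, n_eligible = n_eligible, n_converged = 0L,
        n_pl_coverage = 0L, n_pl_test = 0L,
        bias = NA_real_, bias_mcse = NA_real_,
        relative_bias_pct = NA_real_, relative_bias_mcse = NA_real_,
        modse = NA_real_, empse = NA_real_, rel_se_error_pct = NA_real_,
        rel_se_error_mcse = NA_real_,
        coverage_wald_pct = NA_real_, coverage_wald_mcse = NA_real_,
        coverage_pl_pct = NA_real_, coverage_pl_mcse = NA_real_,
        reject_wald_pct = NA_real_, reject_wald_mcse = NA_real_,
        reject_pl_pct = NA_real_, reject_pl_mcse = NA_real_
      ))
    }

    se_c <- sqrt(rc$v)
    wald_cover_c <- (rc$est - zq * se_c) <= truth & truth <= (rc$est + zq * se_c)
    wald_p_c <- 2 * pnorm(-abs(rc$est / se_c))
    wald_rej_c <- wald_p_c <= alpha

    # profile-likelihood: coverage iff profile deviance at the truth is
    # below the chi-square critical value; rejection iff the deviance at 0
    # reaches it (identical to the CI-bound definition for a concave
    # profile)
    pl_cov_sub <- rc[rc$ok_true, , drop = FALSE]
    pl_tst_sub <- rc[rc$ok_null, , drop = FALSE]
    pl_cover <- pl_cov_sub$dev_true <= crit
    pl_rej <- pl_tst_sub$dev_null >= crit

    if (mode == "converged_only") {
      cover_wald <- mc_coverage(rc$est - zq * se_c, rc$est + zq * se_c, truth)
      cover_wald_n <- n_c
      rej_wald <- mc_rejection_rate(wald_p_c, alpha)
      cover_pl <- if (nrow(pl_cov_sub)) 100 * mean(pl_cover) else NA_real_
      cover_pl_n <- nrow(pl_cov_sub)
      rej_pl <- if (nrow(pl_tst_sub)) 100 * mean(pl_rej) else NA_real_
      rej_pl_n <- nrow(pl_tst_sub)
    } else {
      # non-converged (or profile-failed) replicates cover and do not reject
      cover_wald <- 100 * (sum(wald_cover_c) + (n_eligible - n_c)) / n_eligible
      cover_wald_n <- n_eligible
      rej_wald <- 100 * sum(wald_rej_c) / n_eligible
      cover_pl <- 100 * (sum(pl_cover) + (n_eligible - nrow(pl_cov_sub))) /
        n_eligible
      cover_pl_n <- n_eligible
      rej_pl <- 100 * sum(pl_rej) / n_eligible
      rej_pl_n <- n_eligible
    }

    tibble::tibble(
      method = method, term = term, truth = truth, mode = mode,
      n_generated = n_generated, n_eligible = n_eligible,
      n_converged = n_c,
      n_pl_coverage = nrow(pl_cov_sub), n_pl_test = nrow(pl_tst_sub),
      bias = mc_bias(rc$est, truth),
      bias_mcse = sd(rc$est) / sqrt(n_c),
      relative_bias_pct = if (truth != 0) mc_relative_bias(rc$est, truth)
                          else NA_real_,
      relative_bias_mcse = if (truth != 0)
        100 * sd(rc$est) / (abs(truth) * sqrt(n_c)) else NA_real_,
      modse = sqrt(mean(rc$v)),
      empse = sd(rc$est),
      rel_se_error_pct = mc_rel_se_error(rc$v, rc$est),
      rel_se_error_mcse = rel_se_error_mcse(rc$v, rc$est),
      coverage_wald_pct = cover_wald,
      coverage_wald_mcse = rate_mcse(cover_wald, cover_wald_n),
      coverage_pl_pct = cover_pl,
      coverage_pl_mcse = rate_mcse(cover_pl, cover_pl_n),
      reject_wald_pct = rej_wald,
      reject_wald_mcse = rate_mcse(rej_wald, cover_wald_n),
      reject_pl_pct = rej_pl,
      reject_pl_mcse = rate_mcse(rej_pl, rej_pl_n)
    )
  })
}
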