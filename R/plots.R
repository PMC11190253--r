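#' Plot a scenario-run summary
#'
#' Dot-and-error-bar panels of the converged-only performance measures for
#' the interaction coefficient, by method: relative bias, SE error,
#' coverage and power (Wald vs. profile likelihood).  Error bars are +/- 1
#' Monte-Carlo SE.
#'
#' @param object A [run_scenario()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scenario_run <- function(object, ...) {
  sm <- dplyr::filter(object$summary, .data$term == "MT",
                      .data$mode == "converged_only")
  long <- dplyr::bind_rows(
    tibble::tibble(method = sm$method, measure = "relative bias (%)",
                   value = sm$relative_bias_pct,
                   mcse = sm$relative_bias_mcse, ref = 0),
    tibble::tibble(method = sm$method, measure = "SE error (%)",
                   value = sm$rel_se_error_pct,
                   mcse = sm$rel_se_error_mcse, ref = 0),
    tibble::tibble(method = sm$method, measure = "coverage, Wald (%)",
                   value = sm$coverage_wald_pct,
                   mcse = sm$coverage_wald_mcse, ref = 95),
    tibble::tibble(method = sm$method, measure = "coverage, PL (%)",
                   value = sm$coverage_pl_pct,
                   mcse = sm$coverage_pl_mcse, ref = 95),
    tibble::tibble(method = sm$method, measure = "rejection, Wald (%)",
                   value = sm$reject_wald_pct,
                   mcse = sm$reject_wald_mcse, ref = NA_real_),
    tibble::tibble(method = sm$method, measure = "rejection, PL (%)",
                   value = sm$reject_pl_pct,
                   mcse = sm$reject_pl_mcse, ref = NA_real_)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$value)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$ref),
                        linetype = "dashed", colour = "grey50",
                        na.rm = TRUE) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$value - .data$mcse,
                                          ymax = .data$value + .data$mcse)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Interaction-coefficient performance measures")
}

#' Power curve over sample size
#'
#' Runs [power_sim()] over a vector of sample sizes and plots the estimated
#' power of the interaction test with its Monte-Carlo interval.
#'
#' @param scenario A one-row scenario tibble (its `n` is ignored).
#' @param n_values Sample sizes to evaluate.
#' @param reps Replicates per sample size.
#' @param ... Passed to [power_sim()].
#' @return A ggplot object; the computed tibble is in the `data` element.
#' @export
plot_power_curve <- function(scenario, n_values = c(200, 400, 600, 800,
                                                    1000),
                             reps = 500L, ...) {
  res <- purrr::map_dfr(n_values, function(nn) {
    s <- scenario
    s$n <- as.integer(nn)
    dplyr::mutate(power_sim(s, reps = reps, ...), n = as.integer(nn))
  })
  ggplot2::ggplot(res, ggplot2::aes(x = .data$n, y = .data$power_pct)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mc_lo_pct,
                                      ymax = .data$mc_hi_pct),
                         alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "patients per study", y = "power (%)",
                  title = "Simulation-based power of the interaction test")
}
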