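# per-replicate analysis used by run_scenario(): both parametrizations,
# Wald ingredients, and profile deviances at the truth and at zero for each
# target coefficient.  Works on raw vectors and calls the compiled solver
# directly: this loop runs tens of thousands of times per scenario.
analyze_replicate <- function(raw, truths, method, control) {
  firth <- identical(method, "firth")
  time <- raw$time
  event <- raw$event
  MT <- raw$M * raw$T
  out <- analyze_replicate_skeleton()

  prof_dev <- function(X, j, b, obj_full) {
    binit <- numeric(3)
    binit[j] <- b
    free <- c(1L, 1L, 1L)
    free[j] <- 0L
    pf <- cox_newton_cpp(X, time, event, binit, free, firth,
                         control$maxiter, control$maxstep, control$tol)
    list(dev = max(0, 2 * (obj_full - pf$objective)),
         ok = pf$converged && !pf$singular)
  }

  fill <- function(out, X, fit, terms, cols, truths) {
    for (i in seq_along(terms)) {
      j <- cols[i]
      tm <- terms[i]
      out[[paste0("est_", tm)]] <- fit$coefficients[j]
      out[[paste0("var_", tm)]] <- fit$vcov[j, j]
      p0 <- prof_dev(X, j, 0, fit$objective)
      out[[paste0("dev_null_", tm)]] <- p0$dev
      out[[paste0("ok_null_", tm)]] <- p0$ok
      if (truths[[tm]] == 0) {
        out[[paste0("dev_true_", tm)]] <- p0$dev
        out[[paste0("ok_true_", tm)]] <- p0$ok
      } else {
        pt <- prof_dev(X, j, truths[[tm]], fit$objective)
        out[[paste0("dev_true_", tm)]] <- pt$dev
        out[[paste0("ok_true_", tm)]] <- pt$ok
      }
    }
    out
  }

  b0 <- numeric(3)
  all_free <- c(1L, 1L, 1L)

  Xi <- cbind(raw$M, raw$T, MT)
  fit_int <- cox_newton_cpp(Xi, time, event, b0, all_free, firth,
                            control$maxiter, control$maxstep, control$tol)
  out$conv_int <- fit_int$converged && !fit_int$singular
  if (out$conv_int) out <- fill(out, Xi, fit_int, "MT", 3L, truths)

  Xs <- cbind(raw$M, (1 - raw$M) * raw$T, MT)
  fit_sub <- cox_newton_cpp(Xs, time, event, b0, all_free, firth,
                            control$maxiter, control$maxstep, control$tol)
  out$conv_sub <- fit_sub$converged && !fit_sub$singular
  if (out$conv_sub) {
    out <- fill(out, Xs, fit_sub, c("TM_low", "TM_high"), c(2L, 3L), truths)
  }
  out
}

#' Run the full Monte-Carlo pipeline for one scenario
#'
#' Generates `reps` replicate datasets, applies the eligibility rule (at
#' most one empty marker-treatment event cell), fits the standard and/or
#' Firth-penalized Cox model in both parametrizations, computes Wald
#' ingredients and profile-likelihood deviances, and aggregates the
#' performance measures in both summary modes.
#'
#' @param scenario A one-row scenario tibble.
#' @param reps Number of replicates; defaults to the scenario's `N`.
#' @param methods Estimation methods to run, subset of `c("mple", "firth")`.
#' @param control Solver settings, see [cox_control()].
#' @param alpha Significance level.
#' @param level Confidence level.
#' @param master_seed Master seed; defaults to the scenario's own.
#' @param progress Print a progress line every 1000 replicates?
#' @return An object of class `scenario_run`: list with `scenario`,
#'   `replicates` (one row per replicate x method) and `summary` (one row
#'   per mode x method x coefficient, see [summarize_replicates()]).
#' @examples
#' \donttest{
#' s <- scenario(n = 200, HR_M = 3, HR_I = 0.25)
#' run <- run_scenario(s, reps = 200)
#' dplyr::filter(run$summary, term == "MT", mode == "converged_only")
#' }
#' @export
run_scenario <- function(scenario, reps = scenario$N,
                         methods = c("mple", "firth"),
                         control = cox_control(), alpha = 0.05,
                         level = 0.95,
                         master_seed = scenario$master_seed,
                         progress = FALSE) {
  stopifnot(nrow(scenario) == 1L, all(methods %in% c("mple", "firth")))
  reps <- as.integer(reps)
  s <- scenario_coefs(scenario)
  truths <- c(MT = s$beta_I, TM_low = s$beta_TM_low,
              TM_high = s$beta_TM_high)

  if (reps == 0L) {
    return(structure(
      list(scenario = scenario, replicates = tibble::tibble(),
           summary = tibble::tibble(), n_generated = 0L,
           alpha = alpha, level = level, control = control),
      class = "scenario_run"))
  }

  gen <- make_generator(scenario, master_seed)
  skel <- analyze_replicate_skeleton()
  fields <- names(skel)
  nrow_out <- reps * length(methods)
  cols <- c(list(replicate = integer(nrow_out),
                 method = character(nrow_out),
                 eligible = logical(nrow_out)),
            purrr::map(skel, ~ vector(typeof(.x), nrow_out)))
  k <- 0L
  for (r in seq_len(reps)) {
    raw <- gen(r)
    cell_events <- tabulate((1L + raw$M + 2L * raw$T)[raw$event == 1L],
                            nbins = 4L)
    eligible <- sum(cell_events == 0L) <= 1L
    for (m in methods) {
      k <- k + 1L
      rec <- if (eligible) analyze_replicate(raw, truths, m, control) else
        skel
      cols$replicate[k] <- r
      cols$method[k] <- m
      cols$eligible[k] <- eligible
      for (f in fields) cols[[f]][k] <- rec[[f]]
    }
    if (progress && r %% 1000L == 0L) {
      message(sprintf("  replicate %d / %d", r, reps))
    }
  }
  replicates <- tibble::as_tibble(cols)

  summary <- dplyr::bind_rows(
    summarize_replicates(replicates, scenario, "converged_only",
                         alpha, level),
    summarize_replicates(replicates, scenario, "sensitivity", alpha, level)
  )
  key_cols <- tibble::as_tibble(scenario)[scenario_fields]
  summary <- dplyr::bind_cols(
    summary,
    key_cols[rep(1L, nrow(summary)), ],
    tibble::tibble(scenario_key = scenario_key(scenario))
  )

  structure(
    list(scenario = scenario, replicates = replicates, summary = summary,
         n_generated = reps, alpha = alpha, level = level,
         control = control),
    class = "scenario_run")
}

analyze_replicate_skeleton <- function() {
  out <- list(
    conv_int = FALSE, conv_sub = FALSE,
    est_MT = NA_real_, var_MT = NA_real_,
    est_TM_low = NA_real_, var_TM_low = NA_real_,
    est_TM_high = NA_real_, var_TM_high = NA_real_
  )
  for (tm in c("MT", "TM_low", "TM_high")) {
    out[[paste0("dev_true_", tm)]] <- NA_real_
    out[[paste0("dev_null_", tm)]] <- NA_real_
    out[[paste0("ok_true_", tm)]] <- FALSE
    out[[paste0("ok_null_", tm)]] <- FALSE
  }
  out
}

#' @export
print.scenario_run <- function(x, ...) {
  cat(sprintf("Scenario run: %d replicates\n", x$n_generated))
  if (nrow(x$summary)) {
    print(dplyr::select(
      dplyr::filter(x$summary, .data$mode == "converged_only"),
      "method", "term", "n_converged", "bias", "relative_bias_pct",
      "coverage_wald_pct", "coverage_pl_pct", "reject_wald_pct",
      "reject_pl_pct"), ...)
  }
  invisible(x)
}

#' Simulation-based power of the marker-treatment interaction test
#'
#' Estimates the rejection rate of the test of a zero interaction
#' coefficient under a scenario, for a chosen estimation method and test
#' (Wald or profile-likelihood ratio), with an exact binomial Monte-Carlo
#' confidence interval.  Denominator: eligible replicates with a converged
#' fit (and computable likelihood-ratio statistic for `ci = "pl"`).
#'
#' @param scenario A one-row scenario tibble; `HR_I = 1` gives the type I
#'   error rate.
#' @param reps Number of replicates.
#' @param alpha Significance level of the interaction test.
#' @param method `"mple"` or `"firth"`.
#' @param ci `"pl"` (likelihood-ratio test, penalized for Firth fits) or
#'   `"wald"`.
#' @param control Solver settings.
#' @param master_seed Master seed; defaults to the scenario's own.
#' @param conf.level Level of the Monte-Carlo interval around the power
#'   estimate.
#' @return A one-row tibble: `power_pct`, `mc_lo_pct`, `mc_hi_pct`,
#'   `n_used`, `n_eligible`, `reps`, `method`, `ci`, `alpha`, `degenerate`
#'   (fewer than 2 usable replicates or a 0/100% estimate).
#' @examples
#' \donttest{
#' s <- scenario(n = 400, HR_M = 3, HR_I = 0.25)
#' power_sim(s, reps = 100, method = "firth", ci = "pl")
#' }
#' @export
power_sim <- function(scenario, reps = 1000L, alpha = 0.05,
                      method = c("firth", "mple"), ci = c("pl", "wald"),
                      control = cox_control(),
                      master_seed = scenario$master_seed,
                      conf.level = 0.95) {
  method <- match.arg(method)
  ci <- match.arg(ci)
  stopifnot(nrow(scenario) == 1L, reps >= 1)
  n_eligible <- 0L
  rejected <- logical(0)
  for (r in seq_len(reps)) {
    data <- simulate_dataset(scenario, r, master_seed)
    if (!is_eligible(data)) next
    n_eligible <- n_eligible + 1L
    fit <- cox_fit(data, "interaction", method, control)
    if (!fit$converged) next
    if (ci == "wald") {
      se <- sqrt(fit$vcov["MT", "MT"])
      p <- 2 * pnorm(-abs(fit$coefficients[["MT"]] / se))
    } else {
      lr <- lr_test(fit, "MT")
      if (!lr$converged) next
      p <- lr$lr_p
    }
    rejected <- c(rejected, p <= alpha)
  }
  n_used <- length(rejected)
  x <- sum(rejected)
  est <- if (n_used > 0) 100 * x / n_used else NA_real_
  mc <- if (n_used > 0) {
    100 * as.numeric(stats::binom.test(x, n_used,
                                       conf.level = conf.level)$conf.int)
  } else c(NA_real_, NA_real_)
  tibble::tibble(
    power_pct = est, mc_lo_pct = mc[1], mc_hi_pct = mc[2],
    n_used = n_used, n_eligible = n_eligible, reps = as.integer(reps),
    method = method, ci = ci, alpha = alpha,
    degenerate = n_used < 2 || (n_used > 0 && (x == 0L || x == n_used))
  )
}

#' Published reference values for the three headline result tables
#'
#' Monte-Carlo summaries (10000 replicates per scenario) reported for three
#' scenario families: varying marker effect `HR_M` (0.6 / 1 / 3 with
#' `HR_I = 0.25`, `p_M = 0.25`, `OR_MT = 1`), varying marker prevalence
#' `p_M` (0.25 / 0.5 / 0.75 with `HR_I = 0.75`, `HR_M = 0.8`,
#' `OR_MT = 0.5`), and varying marker-treatment association `OR_MT`
#' (0.5 / 1 / 2 with `HR_I = 0.5`, `HR_M = 1`, `p_M = 0.5`); all with
#' `n` in \{200, 400, 600\}, `HR_T = 1`, `p_T = 0.5`, `p_e = 0.2`,
#' `p_c = 0.2`, `t_end = 5`.
#'
#' @param table One of `"marker_effect"`, `"marker_prevalence"`,
#'   `"treatment_marker_or"`.
#' @return A tibble of reference cells: relative bias (%) of the
#'   interaction coefficient and of its SE, Wald/PL coverage and power (%),
#'   and the number of converged models `N_c`.
#' @export
printed_results <- function(table = c("marker_effect", "marker_prevalence",
                                      "treatment_marker_or")) {
  table <- match.arg(table)
  path <- system.file("extdata", "printed_results.csv", package = "firthint")
  ref <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  dplyr::filter(ref, .data$table == !!table)
}

replicate_table_scenarios <- function(table, N, master_seed) {
  ns <- c(200L, 400L, 600L)
  base <- switch(
    table,
    marker_effect = tidyr::expand_grid(HR_M = c(0.6, 1, 3), n = ns) |>
      dplyr::mutate(HR_I = 0.25, OR_MT = 1, p_M = 0.25),
    marker_prevalence = tidyr::expand_grid(p_M = c(0.25, 0.5, 0.75),
                                           n = ns) |>
      dplyr::mutate(HR_I = 0.75, HR_M = 0.8, OR_MT = 0.5),
    treatment_marker_or = tidyr::expand_grid(OR_MT = c(0.5, 1, 2), n = ns) |>
      dplyr::mutate(HR_I = 0.5, HR_M = 1, p_M = 0.5)
  )
  dplyr::mutate(base, p_T = 0.5, p_e = 0.2, p_c = 0.2, t_end = 5, HR_T = 1,
                N = as.integer(N),
                master_seed = as.integer(master_seed))[, scenario_fields]
}

#' Recompute a published result table at reduced replicate counts
#'
#' Runs every scenario of one of the three headline tables (see
#' [printed_results()]) at `reps` replicates and returns computed and
#' published values side by side, with the binomial / jackknife Monte-Carlo
#' SE of each computed cell.  The default of 2000 replicates keeps a full
#' table tractable on a desktop (the published values use 10000); the
#' Monte-Carlo tolerance widens accordingly.
#'
#' @param table One of `"marker_effect"`, `"marker_prevalence"`,
#'   `"treatment_marker_or"`.
#' @param reps Replicates per scenario.
#' @param master_seed Master seed.
#' @param control,alpha,level Passed to [run_scenario()].
#' @param progress Print one line per scenario?
#' @return A tibble with one row per (scenario, method): computed columns
#'   (`*_sim`), published columns (`*_pub`), and `mcse` columns.
#' @export
replicate_table <- function(table = c("marker_effect", "marker_prevalence",
                                      "treatment_marker_or"),
                            reps = 2000L, master_seed = 1L,
                            control = cox_control(), alpha = 0.05,
                            level = 0.95, progress = FALSE) {
  table <- match.arg(table)
  scen <- replicate_table_scenarios(table, N = reps,
                                    master_seed = master_seed)
  ref <- printed_results(table)
  block <- ref$block_param[1]

  computed <- purrr::map_dfr(seq_len(nrow(scen)), function(i) {
    if (progress) {
      message(sprintf("scenario %d / %d (n = %d)", i, nrow(scen),
                      scen$n[i]))
    }
    run <- run_scenario(scen[i, ], reps = reps, control = control,
                        alpha = alpha, level = level)
    sm <- dplyr::filter(run$summary, .data$term == "MT",
                        .data$mode == "converged_only")
    tibble::tibble(
      block_value = scen[[block]][i], n = scen$n[i], method = sm$method,
      relbias_bI_sim = sm$relative_bias_pct,
      relbias_bI_mcse = sm$relative_bias_mcse,
      relbias_se_bI_sim = sm$rel_se_error_pct,
      relbias_se_bI_mcse = sm$rel_se_error_mcse,
      coverage_wald_sim = sm$coverage_wald_pct,
      coverage_pl_sim = sm$coverage_pl_pct,
      power_wald_sim = sm$reject_wald_pct,
      power_pl_sim = sm$reject_pl_pct,
      power_pl_mcse = sm$reject_pl_mcse,
      N_c_sim = sm$n_converged, reps = reps
    )
  })

  ref_cols <- dplyr::select(
    ref, "block_value", "n", "method",
    relbias_bI_pub = "relbias_bI_pct",
    relbias_se_bI_pub = "relbias_se_bI_pct",
    coverage_wald_pub = "coverage_wald_pct",
    coverage_pl_pub = "coverage_pl_pct",
    power_wald_pub = "power_wald_pct",
    power_pl_pub = "power_pl_pct",
    N_c_pub = "N_c"
  )
  dplyr::left_join(computed, ref_cols, by = c("block_value", "n", "method"))
}

#' Export a scenario-run summary as delimited text
#'
#' One row per (scenario, mode, method, coefficient) in a stable column
#' order: scenario parameters, then counts, then performance measures with
#' their Monte-Carlo SEs.
#'
#' @param run A [run_scenario()] result (or a list of them).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(run, path) {
  runs <- if (inherits(run, "scenario_run")) list(run) else run
  tab <- dplyr::bind_rows(purrr::map(runs, "summary"))
  front <- c("scenario_key", scenario_fields, "mode", "method", "term")
  tab <- tab[, c(front, setdiff(names(tab), front))]
  utils::write.table(tab, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
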