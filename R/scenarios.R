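#' Define a simulation scenario
#'
#' A scenario fixes every quantity needed to simulate one study condition:
#' the study size, the joint distribution of the binary marker `M` and
#' treatment `T`, the exponential event and censoring processes, the true
#' hazard ratios of the proportional-hazards generating model
#' `h(t) = h0(t) * exp(bM*M + bT*T + bI*M*T)`, and the Monte-Carlo settings.
#'
#' @param n Number of subjects per simulated dataset (>= 4).
#' @param p_M Proportion of subjects with high marker level, in (0, 1).
#' @param p_T Proportion of subjects on the experimental treatment, in (0, 1).
#' @param p_e Baseline cumulative event incidence by `t_end` (subjects with
#'   low marker on standard treatment), in \[0, 1).
#' @param p_c Baseline non-administrative censoring fraction by `t_end`,
#'   in \[0, 1); `p_c = 0` means only administrative censoring at `t_end`.
#' @param t_end Follow-up horizon in years (> 0); all subjects still at risk
#'   are administratively censored at `t_end`.
#' @param OR_MT Odds ratio of the marker-treatment association (> 0).
#' @param HR_M Marker hazard ratio under standard treatment (> 0).
#' @param HR_T Treatment hazard ratio at low marker level (> 0).
#' @param HR_I Interaction hazard ratio, the ratio of treatment hazard
#'   ratios at high vs. low marker level (> 0).
#' @param N Number of Monte-Carlo replicates (>= 1).
#' @param master_seed Integer master seed; each replicate derives its own
#'   reproducible substream from it (see [replicate_seed()]).
#'
#' @return A tibble with one row per scenario and one column per parameter.
#'   Arguments are recycled to a common length, so vectors define several
#'   scenarios at once.
#' @seealso [scenario_grid()], [study_presets()], [simulate_dataset()]
#' @examples
#' scenario(n = 200, p_M = 0.25, HR_M = 3, HR_I = 0.25)
#' @export
scenario <- function(n, p_M = 0.25, p_T = 0.5, p_e = 0.2, p_c = 0.2,
                     t_end = 5, OR_MT = 1, HR_M = 1, HR_T = 1, HR_I = 1,
                     N = 10000L, master_seed = 1L) {
  out <- tibble::tibble(
    n = as.integer(n), p_M = p_M, p_T = p_T, p_e = p_e, p_c = p_c,
    t_end = t_end, OR_MT = OR_MT, HR_M = HR_M, HR_T = HR_T, HR_I = HR_I,
    N = as.integer(N), master_seed = as.integer(master_seed)
  )
  validate_scenarios(out)
}

scenario_fields <- c("n", "p_M", "p_T", "p_e", "p_c", "t_end", "OR_MT",
                     "HR_M", "HR_T", "HR_I", "N", "master_seed")

#' Validate a tibble of scenarios
#'
#' Checks ranges (probabilities in their stated intervals, strictly positive
#' ratios, `n >= 4`, `N >= 1`) and that the derived log hazard ratios are
#' finite.  Returns its input invisibly unchanged on success.
#'
#' @param scenarios A data frame with the columns of [scenario()].
#' @return The validated tibble.
#' @export
validate_scenarios <- function(scenarios) {
  scenarios <- tibble::as_tibble(scenarios)
  missing <- setdiff(scenario_fields, names(scenarios))
  if (length(missing)) {
    stop("scenario is missing fields: ", paste(missing, collapse = ", "))
  }
  with(scenarios, {
    stopifnot(
      all(n >= 4), all(N >= 1),
      all(p_M > 0 & p_M < 1), all(p_T > 0 & p_T < 1),
      all(p_e >= 0 & p_e < 1), all(p_c >= 0 & p_c < 1),
      all(t_end > 0),
      all(OR_MT > 0), all(HR_M > 0), all(HR_T > 0), all(HR_I > 0),
      all(is.finite(log(HR_M)) & is.finite(log(HR_T)) & is.finite(log(HR_I)))
    )
  })
  scenarios
}

#' True log hazard-ratio coefficients of a scenario
#'
#' Under the generating model, the interaction parametrization has
#' coefficients `(beta_M, beta_T, beta_I) = log(HR_M, HR_T, HR_I)`, and the
#' subgroup parametrization has treatment effects `beta_TM_low = log(HR_T)`
#' and `beta_TM_high = log(HR_T * HR_I)`.
#'
#' @param scenarios A scenario tibble.
#' @return The input with columns `beta_M`, `beta_T`, `beta_I`,
#'   `beta_TM_low`, `beta_TM_high` added.
#' @export
scenario_coefs <- function(scenarios) {
  dplyr::mutate(
    tibble::as_tibble(scenarios),
    beta_M = log(.data$HR_M),
    beta_T = log(.data$HR_T),
    beta_I = log(.data$HR_I),
    beta_TM_low = log(.data$HR_T),
    beta_TM_high = log(.data$HR_T * .data$HR_I)
  )
}

#' Canonical identity string of a scenario
#'
#' All parameters in a fixed order; used as the reproducible join key in
#' outputs and to derive per-replicate random-number substreams.
#'
#' @param scenarios A scenario tibble.
#' @return A character vector, one key per row.
#' @export
scenario_key <- function(scenarios) {
  s <- tibble::as_tibble(scenarios)[scenario_fields]
  vals <- purrr::map(scenario_fields, function(f) {
    format(s[[f]], trim = TRUE, digits = 15, scientific = FALSE)
  })
  apply(
    matrix(unlist(vals), ncol = length(vals)), 1L,
    function(row) paste(paste0(scenario_fields, "=", row), collapse = "|")
  )
}

#' Cell probabilities of the marker-treatment 2x2 table
#'
#' Returns the unique bivariate Bernoulli distribution of `(M, T)` with
#' margins `P(M = 1) = p_M`, `P(T = 1) = p_T` and odds ratio `OR_MT`
#' (Plackett construction).  For `OR_MT = 1` this is the independence table
#' `p_11 = p_M * p_T`; otherwise `p_11` is the admissible root of the
#' quadratic `theta * (p_M - p_11) * (p_T - p_11) =
#' p_11 * (1 - p_M - p_T + p_11)`:
#' `p_11 = (S - sqrt(S^2 - 4 theta (theta - 1) p_M p_T)) / (2 (theta - 1))`
#' with `S = 1 + (p_M + p_T)(theta - 1)`.
#'
#' @param p_M,p_T Marginal probabilities, in (0, 1).
#' @param OR_MT Odds ratio (> 0).  All arguments are recycled.
#' @return A tibble with columns `p_00`, `p_10`, `p_01`, `p_11` (first index
#'   marker, second treatment), one row per input.
#' @examples
#' cell_probabilities(0.25, 0.5, 2)
#' @export
cell_probabilities <- function(p_M, p_T, OR_MT) {
  k <- vctrs_recycle(p_M = p_M, p_T = p_T, OR_MT = OR_MT)
  p_M <- k$p_M; p_T <- k$p_T; theta <- k$OR_MT
  stopifnot(all(p_M > 0 & p_M < 1), all(p_T > 0 & p_T < 1), all(theta > 0))
  p11 <- ifelse(theta == 1, p_M * p_T, NA_real_)
  gen <- which(theta != 1)
  if (length(gen)) {
    th <- theta[gen]
    S <- 1 + (p_M[gen] + p_T[gen]) * (th - 1)
    disc <- S^2 - 4 * th * (th - 1) * p_M[gen] * p_T[gen]
    if (any(disc < 0)) stop("internal error: negative discriminant")
    p11[gen] <- (S - sqrt(disc)) / (2 * (th - 1))
  }
  out <- tibble::tibble(
    p_00 = 1 - p_M - p_T + p11,
    p_10 = p_M - p11,
    p_01 = p_T - p11,
    p_11 = p11
  )
  if (any(unlist(out) < -1e-12) || any(unlist(out) > 1 + 1e-12)) {
    stop("internal error: cell probability outside [0, 1]")
  }
  out
}

#' Exponential rate matching a cumulative incidence
#'
#' Rate `lambda` of an exponential time such that a fraction `p` of subjects
#' has the event by `t_end`: `lambda = -log(1 - p) / t_end`.  `p = 0` gives
#' rate 0, interpreted by the generator as "no random censoring" (time
#' `+Inf`).
#'
#' @param p Cumulative incidence by `t_end`, in \[0, 1).
#' @param t_end Horizon (> 0).
#' @return Rate(s) per unit time.
#' @examples
#' rate_from_incidence(0.2, 5)
#' @export
rate_from_incidence <- function(p, t_end) {
  stopifnot(all(p >= 0), all(p < 1), all(t_end > 0))
  -log(1 - p) / t_end
}

#' Full factorial grid of simulation conditions
#'
#' Crosses the study-design values used throughout the simulation study:
#' `n` in 200...1000, `p_M` in \{0.25, 0.5, 0.75\}, `p_c` in \{0.2, 0.5\},
#' `OR_MT` in \{0.5, 1, 2\}, `HR_M` in \{0.6, 0.8, 1, 3, 6\} and `HR_I` in
#' \{0.25, 0.5, 0.75, 1\}, holding `N = 10000`, `p_T = 0.5`, `p_e = 0.2`,
#' `t_end = 5` and `HR_T = 1` fixed (qualitative interactions: the
#' experimental treatment has no effect at low marker level).
#'
#' @param master_seed Master seed stamped on every scenario.
#' @return A tibble of 2520 scenarios.
#' @export
scenario_grid <- function(master_seed = 1L) {
  g <- tidyr::expand_grid(
    n = c(200L, 300L, 400L, 500L, 600L, 800L, 1000L),
    p_M = c(0.25, 0.5, 0.75),
    p_c = c(0.2, 0.5),
    OR_MT = c(0.5, 1, 2),
    HR_M = c(0.6, 0.8, 1, 3, 6),
    HR_I = c(0.25, 0.5, 0.75, 1)
  )
  validate_scenarios(dplyr::mutate(
    g,
    p_T = 0.5, p_e = 0.2, t_end = 5, HR_T = 1,
    N = 10000L, master_seed = as.integer(master_seed)
  )[, scenario_fields])
}

#' Scenario presets derived from published breast-cancer studies
#'
#' Parameter sets extracted from five breast-cancer studies of candidate
#' predictive biomarkers (de Boo 2022; Knauer 2010; Kok 2009; Schouten 2016;
#' Vollebergh 2014): unadjusted marker, treatment and interaction hazard
#' ratios with follow-up truncated at 5 years.  Presets with `p_c = 0` have
#' no random censoring (only administrative censoring at `t_end`).
#'
#' @param N,master_seed Monte-Carlo settings stamped on each preset.
#' @return A tibble of five scenarios with a leading `study` column.
#' @export
study_presets <- function(N = 10000L, master_seed = 1L) {
  p <- tibble::tribble(
    ~study,        ~n,   ~p_M, ~p_T, ~p_e, ~p_c, ~OR_MT, ~HR_M, ~HR_T, ~HR_I,
    "deBoo",      129L,  0.53, 0.47, 0.38, 0,    0.92,   0.67,  0.23,  1.95,
    "Knauer",     541L,  0.53, 0.42, 0.03, 0.88, 2.34,   6.60,  0.56,  0.37,
    "Kok",        239L,  0.52, 0.49, 0.40, 0,    1.48,   0.86,  0.83,  0.63,
    "Schouten",   117L,  0.14, 0.59, 0.34, 0.65, 1.70,   5.39,  0.87,  0.08,
    "Vollebergh", 230L,  0.18, 0.49, 0.38, 0,    0.79,   3.51,  0.68,  0.24
  )
  out <- dplyr::mutate(p, t_end = 5, N = as.integer(N),
                       master_seed = as.integer(master_seed))
  validate_scenarios(out[, c("study", scenario_fields)][scenario_fields])
  out[, c("study", scenario_fields)]
}

#' Read scenarios from a plain-text configuration file
#'
#' The file is YAML with one mapping per document, keys exactly the
#' [scenario()] field names.  A key whose value is a list defines a grid
#' axis; list-valued keys are fully crossed.
#'
#' @param path Path to the configuration file.
#' @return A scenario tibble.
#' @export
read_scenarios <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading scenario files requires the 'yaml' package")
  }
  txt <- readLines(path)
  breaks <- c(0L, which(grepl("^---\\s*$", txt)), length(txt) + 1L)
  chunks <- purrr::map(seq_len(length(breaks) - 1L), function(i) {
    txt[seq.int(breaks[i] + 1L, breaks[i + 1L] - 1L)]
  })
  docs <- purrr::compact(purrr::map(chunks, function(ch) {
    if (!length(ch) || all(grepl("^\\s*(#.*)?$", ch))) return(NULL)
    # keep keys like "n" and "N" literal instead of YAML 1.1 booleans
    yaml::yaml.load(paste(ch, collapse = "\n"),
                    handlers = list("bool#yes" = identity,
                                    "bool#no" = identity))
  }))
  defaults <- as.list(formals(scenario))
  rows <- purrr::map(docs, function(doc) {
    unknown <- setdiff(names(doc), scenario_fields)
    if (length(unknown)) stop("unknown scenario keys: ",
                              paste(unknown, collapse = ", "))
    axes <- purrr::map(doc, unlist)
    do.call(tidyr::expand_grid, axes)
  })
  g <- dplyr::bind_rows(rows)
  for (f in setdiff(scenario_fields, names(g))) g[[f]] <- eval(defaults[[f]])
  g$n <- as.integer(g$n); g$N <- as.integer(g$N)
  g$master_seed <- as.integer(g$master_seed)
  validate_scenarios(g[scenario_fields])
}

# minimal common-length recycling for scalar-or-vector arguments
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == len) a else rep(a, length.out = len)
  })
}
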