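#' Derive the random-number seed of one replicate
#'
#' One master seed spawns a dedicated substream per (scenario, replicate),
#' so any replicate can be regenerated without generating its predecessors.
#' The substream seed is `(31 * h + 17 * master_seed + replicate) mod
#' (2^31 - 1)` where `h` is a polynomial byte hash of the scenario key;
#' consecutive replicates of a scenario always get distinct seeds.
#'
#' @param scenario A one-row scenario tibble.
#' @param replicate Replicate index (>= 1).
#' @param master_seed Master seed; defaults to the scenario's own.
#' @return An integer seed for [set.seed()].
#' @export
replicate_seed <- function(scenario, replicate,
                           master_seed = scenario$master_seed) {
  seed_from_hash(scenario_hash(scenario_key(scenario)), master_seed,
                 replicate)
}

scenario_hash <- function(key) {
  m <- 2147483647
  h <- 0
  for (b in utf8ToInt(key)) h <- (h * 131 + b) %% m
  h
}

seed_from_hash <- function(h, master_seed, replicate) {
  m <- 2147483647
  as.integer((31 * h + 17 * (as.numeric(master_seed) %% m) +
                as.numeric(replicate)) %% m)
}

#' Draw marker-treatment cell assignments
#'
#' `n` independent draws from the four-cell multinomial distribution,
#' returned in draw order.
#'
#' @param n Number of subjects.
#' @param probs One row of [cell_probabilities()] (columns `p_00`, `p_10`,
#'   `p_01`, `p_11`).
#' @return A tibble with integer columns `M` and `T`.
#' @export
draw_cells <- function(n, probs) {
  stopifnot(n >= 1, abs(sum(unlist(probs[1, c("p_00", "p_10", "p_01",
                                              "p_11")])) - 1) < 1e-9)
  cell <- sample.int(4L, n, replace = TRUE,
                     prob = c(probs$p_00[1], probs$p_10[1],
                              probs$p_01[1], probs$p_11[1]))
  tibble::tibble(M = as.integer(cell %in% c(2L, 4L)),
                 T = as.integer(cell %in% c(3L, 4L)))
}

#' Latent event time by inverse-transform sampling
#'
#' `t_e = -log(u) / (lambda_e * exp(beta_M * M + beta_T * T + beta_I * M * T))`,
#' an exponential time whose rate follows the proportional-hazards
#' generating model.
#'
#' @param M,T Binary marker and treatment indicators.
#' @param lambda_e Baseline event rate (> 0).
#' @param beta_M,beta_T,beta_I Log hazard ratios.
#' @param u Uniform draws on the open interval (0, 1).
#' @return Strictly positive event times.
#' @export
event_time <- function(M, T, lambda_e, beta_M, beta_T, beta_I, u) {
  stopifnot(lambda_e > 0, all(u > 0), all(u <= 1))
  -log(u) / (lambda_e * exp(beta_M * M + beta_T * T + beta_I * M * T))
}

#' Latent censoring time
#'
#' Exponential with rate `lambda_c`, independent of marker and treatment
#' (non-differential censoring).  Rate 0 returns `+Inf`: only administrative
#' censoring applies.
#'
#' @param lambda_c Censoring rate (>= 0).
#' @param u Uniform draws on (0, 1).
#' @return Censoring times (possibly `Inf`).
#' @export
censoring_time <- function(lambda_c, u) {
  stopifnot(lambda_c >= 0, all(u > 0), all(u <= 1))
  if (lambda_c == 0) rep(Inf, length(u)) else -log(u) / lambda_c
}

#' Simulate one replicate dataset from a scenario
#'
#' Draws cell assignments, latent event and censoring times, and applies
#' administrative censoring at `t_end`: a subject with `t_e <= min(t_c,
#' t_end)` has an event at `t_e`, otherwise is censored at `min(t_c,
#' t_end)`.  Fully deterministic given `(master_seed, scenario,
#' replicate)`.
#'
#' @param scenario A one-row scenario tibble.
#' @param replicate Replicate index (>= 1).
#' @param master_seed Master seed; defaults to the scenario's own.
#' @return A tibble with columns `M`, `T` (integer 0/1), `time` (years) and
#'   `event` (integer 0/1), carrying attributes `scenario_key` and
#'   `replicate`.
#' @examples
#' s <- scenario(n = 200, HR_M = 3, HR_I = 0.25)
#' d <- simulate_dataset(s, replicate = 1)
#' table(d$M, d$T)
#' @export
simulate_dataset <- function(scenario, replicate = 1L,
                             master_seed = scenario$master_seed) {
  stopifnot(nrow(scenario) == 1L, replicate >= 1)
  gen <- make_generator(scenario, master_seed)
  raw <- gen(replicate)
  out <- tibble::tibble(M = raw$M, T = raw$T, time = raw$time,
                        event = raw$event)
  attr(out, "scenario_key") <- scenario_key(scenario)
  attr(out, "replicate") <- as.integer(replicate)
  out
}

# precomputed fast path shared by simulate_dataset() and run_scenario():
# returns a closure generating the raw vectors of one replicate
make_generator <- function(scenario, master_seed = scenario$master_seed) {
  s <- scenario_coefs(validate_scenarios(scenario))
  probs <- cell_probabilities(s$p_M, s$p_T, s$OR_MT)
  pvec <- c(probs$p_00, probs$p_10, probs$p_01, probs$p_11)
  lambda_e <- rate_from_incidence(s$p_e, s$t_end)
  lambda_c <- rate_from_incidence(s$p_c, s$t_end)
  h <- scenario_hash(scenario_key(scenario))
  n <- s$n
  t_end <- s$t_end
  rate_mult <- lambda_e * exp(c(0, s$beta_M, s$beta_T,
                                s$beta_M + s$beta_T + s$beta_I))
  function(replicate) {
    set.seed(seed_from_hash(h, master_seed, replicate))
    cell <- sample.int(4L, n, replace = TRUE, prob = pvec)
    u_e <- open_unif(n)
    u_c <- open_unif(n)
    t_e <- -log(u_e) / rate_mult[cell]
    horizon <- if (lambda_c > 0) pmin(-log(u_c) / lambda_c, t_end) else
      rep(t_end, n)
    event <- t_e <= horizon
    list(M = as.integer(cell == 2L | cell == 4L),
         T = as.integer(cell == 3L | cell == 4L),
         time = ifelse(event, t_e, horizon),
         event = as.integer(event))
  }
}

# uniforms restricted to the open interval (0, 1): -log(u) stays finite and
# strictly positive, so no zero-length follow-up records
open_unif <- function(n) {
  u <- runif(n)
  pmin(pmax(u, .Machine$double.eps), 1 - .Machine$double.eps)
}

#' Count events per marker-treatment cell
#'
#' @param data A dataset with columns `M`, `T`, `event`.
#' @return A tibble with one row per cell (`M`, `T`, `events`), all four
#'   cells always present.
#' @export
events_per_cell <- function(data) {
  idx <- 1L + data$M + 2L * data$T  # cells (0,0), (1,0), (0,1), (1,1)
  counts <- tabulate(idx[data$event == 1L], nbins = 4L)
  tibble::tibble(M = c(0L, 1L, 0L, 1L), T = c(0L, 0L, 1L, 1L),
                 events = counts)
}

#' Eligibility of a simulated dataset
#'
#' A dataset is eligible for analysis if at most one of the four
#' marker-treatment cells has zero events; with two or more empty event
#' cells the interaction model is unidentifiable in more than one direction
#' and the dataset is excluded from all summaries, irrespective of model
#' convergence.
#'
#' @param data A dataset with columns `M`, `T`, `event`.
#' @return `TRUE` or `FALSE`.
#' @export
is_eligible <- function(data) {
  sum(events_per_cell(data)$events == 0L) <= 1L
}

#' Write a simulated dataset as delimited text
#'
#' Tab-separated with header `M T time event`, consumable by any survival
#' software for cross-checking.
#'
#' @param data A dataset tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.table(data[, c("M", "T", "time", "event")], path,
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
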