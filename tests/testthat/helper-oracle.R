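# Independent oracles used across the test files.  None of these share code
# with the package's estimation path.

# Breslow partial log-likelihood by direct risk-set enumeration (plain R,
# any design matrix); censored subjects at t stay at risk for events at t.
oracle_partial_loglik <- function(X, time, event, beta) {
  eta <- drop(X %*% beta)
  w <- exp(eta)
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + eta[i] - log(sum(w[risk]))
  }
  ll
}

# observed information at beta by central finite differences of the
# enumeration log-likelihood
oracle_information <- function(X, time, event, beta, h = 1e-4) {
  p <- length(beta)
  H <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      bpp <- bpm <- bmp <- bmm <- beta
      bpp[a] <- bpp[a] + h; bpp[b] <- bpp[b] + h
      bpm[a] <- bpm[a] + h; bpm[b] <- bpm[b] - h
      bmp[a] <- bmp[a] - h; bmp[b] <- bmp[b] + h
      bmm[a] <- bmm[a] - h; bmm[b] <- bmm[b] - h
      H[a, b] <- (oracle_partial_loglik(X, time, event, bpp) -
                    oracle_partial_loglik(X, time, event, bpm) -
                    oracle_partial_loglik(X, time, event, bmp) +
                    oracle_partial_loglik(X, time, event, bmm)) / (4 * h * h)
    }
  }
  -(H + t(H)) / 2
}

# Firth-penalized objective from the enumeration log-likelihood and the
# finite-difference information
oracle_penalized_loglik <- function(X, time, event, beta) {
  I <- oracle_information(X, time, event, beta)
  d <- det(I)
  if (d <= 0) return(-Inf)
  oracle_partial_loglik(X, time, event, beta) + 0.5 * log(d)
}

# closed-form objectives of the canonical two-subject dataset
# (x = (1, 0), events at times 1 and 2)
toy_loglik <- function(b) b - log(exp(b) + 1)
toy_penalized <- function(b) 1.5 * b - 2 * log(1 + exp(b))

# simulated datasets for oracle-equivalence sweeps
oracle_datasets <- function(k, n = 150, seed = 42) {
  scen <- scenario(n = n, p_M = 0.4, p_T = 0.5, p_e = 0.45, p_c = 0.2,
                   OR_MT = 1.5, HR_M = 2, HR_T = 0.8, HR_I = 0.6,
                   master_seed = seed)
  lapply(seq_len(k), function(r) simulate_dataset(scen, r))
}
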