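two_subject <- tibble::tibble(M = c(1L, 0L), T = c(0L, 0L),
                              time = c(1, 2), event = c(1L, 1L))
toy_X <- matrix(c(1, 0), ncol = 1, dimnames = list(NULL, "x"))

test_that("partial likelihood matches the hand-expanded two-subject case", {
  for (b in c(-1, 0, 0.7, 2)) {
    e <- firthint:::cox_eval_cpp(toy_X, c(1, 2), c(1L, 1L), b, FALSE)
    expect_equal(e$loglik, toy_loglik(b), tolerance = 1e-12)
    p <- exp(b) / (1 + exp(b))
    expect_equal(drop(e$score), 1 - p, tolerance = 1e-12)
    expect_equal(drop(e$info), p * (1 - p), tolerance = 1e-12)
  }
  e0 <- firthint:::cox_eval_cpp(toy_X, c(1, 2), c(1L, 1L), 0, FALSE)
  expect_equal(drop(e0$score), 0.5)
  expect_equal(drop(e0$info), 0.25)
})

test_that("score at the null is the sum of event-wise covariate residuals", {
  d <- oracle_datasets(1)[[1]]
  X <- design_matrix(d, "interaction")
  ll <- cox_loglik(d, c(0, 0, 0))
  manual <- colSums(do.call(rbind, lapply(which(d$event == 1), function(i) {
    risk <- d$time >= d$time[i]
    X[i, ] - colMeans(X[risk, , drop = FALSE])
  })))
  expect_equal(ll$score, unname(manual), ignore_attr = TRUE,
               tolerance = 1e-10)
})

test_that("analytic score and information match finite differences", {
  d <- oracle_datasets(1)[[1]]
  X <- design_matrix(d, "interaction")
  tm <- d$time
  ev <- as.integer(d$event)
  for (beta in list(c(0, 0, 0), c(0.5, -0.3, 0.8))) {
    e <- firthint:::cox_eval_cpp(X, tm, ev, beta, FALSE)
    h <- 1e-5
    fd <- sapply(1:3, function(j) {
      bp <- bm <- beta
      bp[j] <- bp[j] + h
      bm[j] <- bm[j] - h
      (firthint:::cox_eval_cpp(X, tm, ev, bp, FALSE)$loglik -
         firthint:::cox_eval_cpp(X, tm, ev, bm, FALSE)$loglik) / (2 * h)
    })
    expect_equal(drop(e$score), fd, tolerance = 1e-6)
    expect_equal(e$info, oracle_information(X, tm, ev, beta),
                 tolerance = 1e-4, ignore_attr = TRUE)
  }
})

test_that("the Firth-modified score is the gradient of the penalized objective", {
  d <- oracle_datasets(1)[[1]]
  X <- design_matrix(d, "interaction")
  tm <- d$time
  ev <- as.integer(d$event)
  beta <- c(0.4, -0.2, 0.3)
  e <- firthint:::cox_eval_cpp(X, tm, ev, beta, TRUE)
  h <- 1e-5
  fd <- sapply(1:3, function(j) {
    bp <- bm <- beta
    bp[j] <- bp[j] + h
    bm[j] <- bm[j] - h
    (firthint:::cox_eval_cpp(X, tm, ev, bp, TRUE)$objective -
       firthint:::cox_eval_cpp(X, tm, ev, bm, TRUE)$objective) / (2 * h)
  })
  expect_equal(drop(e$grad_objective), fd, tolerance = 1e-6)
  # penalized value agrees with the enumeration + FD-Hessian oracle
  expect_equal(e$objective, oracle_penalized_loglik(X, tm, ev, beta),
               tolerance = 1e-5)
})

test_that("monotone likelihood: standard fit diverges, Firth fit is log 3", {
  r_mple <- firthint:::cox_newton(toy_X, c(1, 2), c(1L, 1L), "mple")
  expect_false(r_mple$converged)

  r_firth <- firthint:::cox_newton(toy_X, c(1, 2), c(1L, 1L), "firth")
  expect_true(r_firth$converged)
  expect_equal(unname(r_firth$coefficients), log(3), tolerance = 1e-6)
  # stationarity of the modified score at the maximizer
  e <- firthint:::cox_eval_cpp(toy_X, c(1, 2), c(1L, 1L),
                               r_firth$coefficients, TRUE)
  expect_lt(abs(drop(e$grad_objective)), 1e-6)
  # closed-form check of the penalized objective itself
  expect_equal(e$objective, unname(toy_penalized(r_firth$coefficients)),
               tolerance = 1e-10)
})

test_that("mple fits agree with survival::coxph on 50 generated datasets", {
  skip_if_not_installed("survival")
  datasets <- oracle_datasets(50)
  for (d in datasets) {
    f <- cox_fit(d, "interaction", "mple")
    expect_true(f$converged)
    cp <- suppressWarnings(survival::coxph(
      survival::Surv(time, event) ~ M + T + I(M * T), data = d,
      ties = "breslow",
      control = survival::coxph.control(eps = 1e-12, iter.max = 100)))
    expect_equal(unname(f$coefficients), unname(coef(cp)),
                 tolerance = 1e-5)
    expect_equal(unname(sqrt(diag(f$vcov))), unname(sqrt(diag(vcov(cp)))),
                 tolerance = 1e-5)
  }
})

test_that("Firth fits agree with an independent numerical maximizer", {
  set.seed(12)
  scen <- scenario(n = 40, p_e = 0.5, HR_M = 2, HR_I = 0.5)
  for (r in 1:3) {
    d <- simulate_dataset(scen, r)
    X <- design_matrix(d, "interaction")
    f <- cox_fit(d, "interaction", "firth")
    expect_true(f$converged)
    opt <- optim(numeric(3), function(b)
      -oracle_penalized_loglik(X, d$time, as.integer(d$event), b),
      method = "Nelder-Mead",
      control = list(maxit = 5000, reltol = 1e-14))
    expect_equal(unname(f$coefficients), unname(opt$par), tolerance = 1e-3)
    expect_equal(f$objective,
                 oracle_penalized_loglik(X, d$time,
                                         as.integer(d$event),
                                         f$coefficients),
                 tolerance = 1e-6)
  }
})

test_that("Newton solutions match brute-force grid maximization on tiny data", {
  set.seed(23)
  checked <- 0L
  for (i in 1:6) {
    n <- sample(4:8, 1)
    x <- matrix(round(runif(n), 2), ncol = 1)
    tm <- sort(rexp(n), decreasing = FALSE)
    ev <- as.integer(runif(n) < 0.8)
    if (sum(ev) < 2) ev[1:2] <- 1L
    grid <- seq(-4, 4, by = 1e-4)
    # firth objective on the grid via the enumeration oracle
    exact_info <- function(b) {
      e <- 0
      for (j in which(ev == 1)) {
        risk <- tm >= tm[j]
        w <- exp(x[risk, 1] * b)
        m1 <- sum(w * x[risk, 1]) / sum(w)
        m2 <- sum(w * x[risk, 1]^2) / sum(w)
        e <- e + (m2 - m1^2)
      }
      e
    }
    vals <- vapply(grid, function(b) {
      oracle_partial_loglik(x, tm, ev, b) + 0.5 * log(exact_info(b))
    }, numeric(1))
    b_grid <- grid[which.max(vals)]
    r <- firthint:::cox_newton(x, tm, ev, "firth",
                               control = cox_control(maxstep = 0.05))
    if (r$converged && abs(b_grid) < 3.9) {
      checked <- checked + 1L
      expect_lt(abs(unname(r$coefficients) - b_grid), 2e-4)
    }
  }
  expect_gte(checked, 3L)
})

test_that("estimates are invariant to rescaling time", {
  d <- oracle_datasets(1)[[1]]
  d2 <- dplyr::mutate(d, time = time * 17.3)
  for (m in c("mple", "firth")) {
    f1 <- cox_fit(d, "interaction", m)
    f2 <- cox_fit(d2, "interaction", m)
    expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  }
})

test_that("convergence requires the score tolerance within the step budget", {
  d <- oracle_datasets(1)[[1]]
  f <- cox_fit(d, "interaction", "mple", cox_control(maxiter = 3))
  expect_false(f$converged)
  expect_equal(f$iterations, 3L)
  f2 <- cox_fit(d, "interaction", "mple")
  expect_true(f2$converged)
  expect_lt(max(abs(f2$score)), 1e-6)
  expect_lt(f2$iterations, f2$control$maxiter)
  # covariance is symmetric positive definite at the optimum
  expect_equal(f2$vcov, t(f2$vcov))
  expect_true(all(eigen(f2$vcov, symmetric = TRUE)$values > 0))
})

test_that("parameter recovery at large n", {
  s <- scenario(n = 1e5, HR_M = 3, HR_T = 1, HR_I = 0.25, master_seed = 1L)
  d <- simulate_dataset(s, 1)
  f <- cox_fit(d, "interaction", "mple")
  expect_true(f$converged)
  expect_lt(max(abs(f$coefficients - c(log(3), 0, log(0.25)))), 0.02)
})
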