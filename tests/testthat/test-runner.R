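test_that("zero-replicate runs return an empty summary", {
  s <- scenario(n = 200)
  run <- run_scenario(s, reps = 0)
  expect_equal(run$n_generated, 0L)
  expect_equal(nrow(run$summary), 0L)
})

test_that("identical manifests give identical outputs", {
  s <- scenario(n = 150, HR_M = 3, HR_I = 0.25, master_seed = 7L)
  a <- run_scenario(s, reps = 40)
  b <- run_scenario(s, reps = 40)
  expect_equal(a$summary, b$summary)
  expect_equal(a$replicates, b$replicates)
  path1 <- withr::local_tempfile(fileext = ".csv")
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_summary(a, path1)
  write_summary(b, path2)
  expect_identical(readLines(path1), readLines(path2))
  # a different master seed changes the replicates
  c2 <- run_scenario(s, reps = 40, master_seed = 8L)
  expect_false(isTRUE(all.equal(a$summary$bias, c2$summary$bias)))
})

test_that("runs complete and report counts when most datasets are ineligible", {
  # very low event incidence: most replicates have > 1 empty event cell
  s <- scenario(n = 25, p_e = 0.05, p_M = 0.5, master_seed = 2L)
  run <- run_scenario(s, reps = 60)
  sm <- dplyr::filter(run$summary, term == "MT",
                      mode == "converged_only", method == "mple")
  expect_lt(sm$n_eligible, 30)
  expect_equal(sm$n_generated, 60L)
  expect_true(all(run$summary$n_converged <= run$summary$n_eligible))
})

test_that("run_scenario matches an independent per-replicate reanalysis", {
  # the vectorized pipeline agrees with fitting the same datasets through
  # the user-facing single-fit interface
  s <- scenario(n = 200, HR_M = 3, HR_I = 0.25, master_seed = 21L)
  run <- run_scenario(s, reps = 12, methods = "mple")
  for (r in c(3L, 8L)) {
    d <- simulate_dataset(s, r)
    row <- dplyr::filter(run$replicates, replicate == r)
    expect_equal(row$eligible, is_eligible(d))
    f <- cox_fit(d, "interaction", "mple")
    expect_equal(row$conv_int, f$converged)
    if (f$converged) {
      expect_equal(row$est_MT, unname(f$coefficients["MT"]),
                   tolerance = 1e-10)
      expect_equal(row$var_MT, f$vcov["MT", "MT"], tolerance = 1e-10)
      expect_equal(row$dev_null_MT, lr_test(f, "MT")$statistic,
                   tolerance = 1e-8)
    }
  }
})

test_that("power estimates calibrate to alpha under the null", {
  s <- scenario(n = 400, HR_M = 1, HR_T = 1, HR_I = 1, master_seed = 4L)
  pw <- power_sim(s, reps = 400, method = "mple", ci = "wald")
  # null rejection rate near alpha = 5% within 3 binomial SEs
  expect_lt(abs(pw$power_pct - 5), 3 * sqrt(0.05 * 0.95 / pw$n_used) * 100)
  expect_false(pw$degenerate)

  one <- power_sim(s, reps = 1, method = "mple", ci = "wald")
  expect_true(one$degenerate)
  expect_true(one$power_pct %in% c(0, 100) || is.na(one$power_pct))
})

test_that("power is nondecreasing in sample size within Monte-Carlo error", {
  res <- purrr::map_dfr(c(200L, 600L, 1000L), function(nn) {
    s <- scenario(n = nn, HR_M = 3, HR_I = 0.25, master_seed = 6L)
    dplyr::mutate(power_sim(s, reps = 250, method = "firth", ci = "pl"),
                  n = nn)
  })
  se <- sqrt(res$power_pct / 100 * (1 - res$power_pct / 100) /
               res$n_used) * 100
  tol <- 3 * sqrt(se[-1]^2 + se[-3]^2)
  expect_true(all(diff(res$power_pct) > -tol))
  expect_gt(res$power_pct[3], res$power_pct[1])
})

test_that("published reference cells load and join to recomputed tables", {
  ref <- printed_results("marker_effect")
  expect_equal(nrow(ref), 18L)
  expect_setequal(unique(ref$method), c("mple", "firth"))
  expect_equal(
    dplyr::filter(ref, block_value == 3, n == 200, method == "mple")$N_c,
    9724)

  tab <- replicate_table("treatment_marker_or", reps = 30, master_seed = 3L)
  expect_equal(nrow(tab), 18L)
  expect_true(all(!is.na(tab$power_pl_pub)))
  expect_true(all(!is.na(tab$power_pl_sim)))
  expect_true(all(tab$N_c_sim <= 30))
})

test_that("the grid runner covers the documented table scenarios", {
  s3 <- firthint:::replicate_table_scenarios("marker_effect", 10, 1)
  expect_setequal(unique(s3$HR_M), c(0.6, 1, 3))
  expect_setequal(unique(s3$n), c(200L, 400L, 600L))
  s4 <- firthint:::replicate_table_scenarios("marker_prevalence", 10, 1)
  expect_setequal(unique(s4$p_M), c(0.25, 0.5, 0.75))
  s5 <- firthint:::replicate_table_scenarios("treatment_marker_or", 10, 1)
  expect_setequal(unique(s5$OR_MT), c(0.5, 1, 2))
  expect_error(replicate_table("t9"))
})

test_that("plot helpers return ggplot objects", {
  s <- scenario(n = 200, HR_M = 3, HR_I = 0.25, master_seed = 10L)
  run <- run_scenario(s, reps = 30)
  expect_s3_class(autoplot(run), "ggplot")
  p <- plot_power_curve(s, n_values = c(200, 400), reps = 20,
                        method = "firth", ci = "wald")
  expect_s3_class(p, "ggplot")
})
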