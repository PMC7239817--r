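test_that("block-correlation calibration matches the closed form and rejects infeasible targets", {
  cal <- calibrate_block_correlations(92, c(31, 31, 30), 0.25, 0.48)
  expect_equal(cal$top3_var, 0.48, tolerance = 1e-8)
  expect_equal(cal$mean_r, 0.25, tolerance = 1e-8)
  expect_true(cal$within > cal$between && cal$between > 0)
  ## closed form: top-3 share (3 + (p-3) w) / p
  expect_equal((3 + 89 * cal$within) / 92, 0.48, tolerance = 1e-10)

  ## degenerate single-component case: equal blocks, b = w = r
  p <- 30; r <- 0.4
  cal2 <- calibrate_block_correlations(p, c(10, 10, 10), r,
                                       (3 + (p - 3) * r) / p)
  expect_equal(cal2$within, r, tolerance = 1e-8)
  expect_equal(cal2$between, r, tolerance = 1e-8)

  ## infeasible: top-3 of 4 variables at r = 0.9 must exceed 0.2
  expect_error(calibrate_block_correlations(4, c(2, 1, 1), 0.9, 0.2),
               "infeasible")
})

test_that("marker generator reproduces planted ratios and the calibrated correlation structure", {
  cfg <- cohort_config(seed = 5)
  n <- 10000
  set.seed(11)
  sev <- rnorm(n)
  grp <- rep(c("HF", "control"), each = n / 2)
  X <- simulate_markers(cfg, sev, grp)
  expect_true(all(X > 0))
  panel <- cfg$marker_panel
  ## planted Gal-4 ratio 2.5 recovered from group means
  g4 <- panel$column[panel$name == "Gal-4"]
  est <- mean(X[grp == "HF", g4]) / mean(X[grp == "control", g4])
  expect_equal(est, 2.5, tolerance = 0.15)
  ## empirical mean pairwise log-scale correlation within 0.02 of 0.25
  ## (HF half; the planted severity loadings perturb the block value by
  ## under 0.01)
  R <- cor(log(X[grp == "HF", ]))
  expect_lt(abs(mean(R[upper.tri(R)]) - 0.25), 0.02)

  ## unit effect profile: all group ratios ~ 1
  cfg0 <- cfg
  cfg0$marker_panel$ratio[] <- 1
  cfg0$marker_panel$severity_loading[] <- 0
  X0 <- simulate_markers(cfg0, sev, grp)
  ratios <- colMeans(X0[grp == "HF", ]) / colMeans(X0[grp == "control", ])
  expect_lt(max(abs(log(ratios))), 0.15)
})

test_that("physiology generator hits group medians and severity coupling scales linearly", {
  cfg <- cohort_config(seed = 5)
  n <- 10000
  set.seed(12)
  sev <- rnorm(n)
  hf <- simulate_physiology(cfg, sev, rep("HF", n))
  expect_equal(median(hf[, "vo2peak"]), 13.4, tolerance = 0.15)
  expect_equal(median(hf[, "lvef"]), 25, tolerance = 0.5)
  expect_equal(hf[, "pct_inactive"], 100 - hf[, "pct_active"])
  ct <- simulate_physiology(cfg, sev, rep("control", n))
  expect_equal(median(ct[, "vo2peak"]), 23.8, tolerance = 0.25)

  ## doubling the capacity coupling doubles cov(vo2peak, severity)
  cfg2 <- cfg
  cfg2$severity_coupling["physical_capacity"] <-
    2 * cfg$severity_coupling["physical_capacity"]
  hf2 <- simulate_physiology(cfg2, sev, rep("HF", n))
  expect_equal(cov(hf2[, "vo2peak"], sev) / cov(hf[, "vo2peak"], sev),
               2, tolerance = 0.1)

  ## zero coupling decouples physiology from severity
  cfg0 <- cfg
  cfg0$severity_coupling[] <- 0
  hf0 <- simulate_physiology(cfg0, sev, rep("HF", n))
  expect_lt(max(abs(cor(hf0[, c("vo2peak", "lvef", "pct_active")], sev))),
            0.04)
})

test_that("survival generator obeys the exponential closed form and null hazard", {
  cfg <- cohort_config(seed = 5)
  ## shape = 1, gamma = 0, no censoring: median = ln 2 / lambda
  cfg1 <- cfg
  cfg1$hazard_shape <- 1
  cfg1$severity_log_hazard <- 0
  cfg1$baseline_hazard <- 0.5
  cfg1$censor_time <- 1e9
  cfg1$entry_spread <- 0
  set.seed(13)
  s <- simulate_survival(cfg1, rnorm(40000), rep("HF", 40000))
  expect_true(all(s$event == 1))
  expect_equal(median(s$time), log(2) / 0.5, tolerance = 0.03)

  ## gamma = 0: marker quartiles carry no hazard (null Cox HR ~ 1)
  cfg0 <- cfg
  cfg0$severity_log_hazard <- 0
  set.seed(14)
  n <- 2000
  sev <- rnorm(n)
  s0 <- simulate_survival(cfg0, sev, rep("HF", n))
  mk <- exp(0.8 * sev + rnorm(n))
  fit <- fit_cox(s0$time, s0$event,
                 cbind(quartile = quartile_encode(log2(mk))))
  expect_equal(fit$hr[[1]], 1, tolerance = 0.08)

  ## times bounded by the censoring window
  set.seed(15)
  s2 <- simulate_survival(cfg, rnorm(500), rep("HF", 500))
  expect_true(all(s2$time > 0 & s2$time <= cfg$censor_time))
  expect_true(all(s2$event %in% 0:1))
})

test_that("simulate_cohort is deterministic and serialises byte-identically", {
  a <- simulate_cohort(cohort_config(seed = 99))
  b <- simulate_cohort(cohort_config(seed = 99))
  expect_identical(a$table, b$table)
  d1 <- file.path(tempdir(), "coh_a"); d2 <- file.path(tempdir(), "coh_b")
  write_cohort(a, d1); write_cohort(b, d2)
  expect_identical(readLines(file.path(d1, "cohort.tsv")),
                   readLines(file.path(d2, "cohort.tsv")))
  expect_identical(readLines(file.path(d1, "ground_truth.json")),
                   readLines(file.path(d2, "ground_truth.json")))
  ## round trip preserves values
  rt <- read_cohort(d1)
  expect_equal(rt$table$time, a$table$time)
  expect_equal(dim(rt$table), dim(a$table))

  c2 <- simulate_cohort(cohort_config(seed = 100))
  expect_false(identical(a$table$time, c2$table$time))

  ## default shape: 94 rows, 92 marker columns
  expect_equal(nrow(a$table), 94)
  expect_equal(length(marker_columns(a)), 92)
  expect_true(all(as.matrix(a$table[, marker_columns(a)]) > 0))

  ## planted truth names existing entities
  expect_true(all(a$truth$planted_edges$marker %in% names(a$table)))
})

test_that("single-group cohorts are generated but refuse two-class stages", {
  coh <- simulate_cohort(cohort_config(n_hf = 0, n_ctrl = 20, seed = 3))
  expect_equal(nrow(coh$table), 20)
  X <- log2(as.matrix(coh$table[, marker_columns(coh)]))
  expect_error(fit_opls(X, coh$table$group), "two classes")
  expect_error(univariate_screen(coh$table[, marker_columns(coh)],
                                 coh$table$group), "two groups")
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(cluster_sizes = c(40, 40, 40)), "sum")
  expect_error(cohort_config(within_corr = 0.2, between_corr = 0.3),
               "between_corr < within_corr")
  expect_error(cohort_config(baseline_hazard = -1), "positive")
  expect_error(cohort_config(censor_time = -1), "positive")
})
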