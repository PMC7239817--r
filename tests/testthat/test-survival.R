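test_that("quartile coding: hand values, rank invariance, degenerate error", {
  expect_equal(quartile_encode(1:8), c(1, 1, 2, 2, 3, 3, 4, 4))
  set.seed(61)
  v <- rexp(101)
  expect_equal(quartile_encode(v), quartile_encode(log2(v)))
  expect_equal(quartile_encode(v), quartile_encode(rank(v)))
  expect_error(quartile_encode(rep(c(1, 2, 3), 5)), "4 distinct")
  ## values exactly on a type-7 boundary go to the lower quartile
  ## (quartiles of 0:4 are 1, 2, 3)
  expect_equal(quartile_encode(0:4), c(1, 1, 2, 3, 4))
})

test_that("Cox fit matches the grid-search partial-likelihood oracle on all tiny datasets", {
  ## deterministic family of single-covariate datasets with n <= 6,
  ## covering ties, censoring, binary and continuous covariates
  set.seed(62)
  count <- 0
  for (n in 3:6) {
    for (rep_i in 1:6) {
      time <- sample(c(1, 1, 2, 3, 3, 4), n, replace = TRUE)
      event <- rbinom(n, 1, 0.7)
      if (sum(event) == 0) event[1] <- 1
      x <- if (rep_i %% 2) rnorm(n) else sample(0:1, n, replace = TRUE)
      if (length(unique(x)) < 2) next
      fit <- fit_cox(time, event, cbind(x = x))
      if (length(fit$warnings)) next  # monotone likelihoods have no
                                      # finite optimum to compare
      oracle <- oracle_cox_beta(time, event, x)
      expect_equal(unname(fit$beta), oracle, tolerance = 1e-4)
      count <- count + 1
    }
  }
  expect_gt(count, 10)

  ## 4-subject all-event fixtures with an interior maximum (alternating
  ## binary covariates avoid the monotone likelihood of a covariate
  ## perfectly ordered with the event times); plus a tied-time variant
  fit4 <- fit_cox(c(1, 2, 3, 4), rep(1, 4), cbind(x = c(0, 1, 0, 1)))
  expect_equal(unname(fit4$beta),
               oracle_cox_beta(c(1, 2, 3, 4), rep(1, 4), c(0, 1, 0, 1)),
               tolerance = 1e-4)
  fit4t <- fit_cox(c(1, 1, 2, 3), rep(1, 4), cbind(x = c(0, 1, 1, 0)))
  expect_equal(unname(fit4t$beta),
               oracle_cox_beta(c(1, 1, 2, 3), rep(1, 4), c(0, 1, 1, 0)),
               tolerance = 1e-4)
})

test_that("Cox fit agrees with the survival package to 1e-6 on random datasets", {
  skip_if_not_installed("survival")
  set.seed(63)
  for (i in 1:50) {
    n <- sample(30:80, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    tt <- rexp(n, exp(0.4 * X[, 1]))
    cc <- rexp(n, 0.3)
    time <- pmin(tt, cc); event <- as.integer(tt <= cc)
    if (sum(event) < p + 2) next
    ## induce ties in a third of the datasets
    if (i %% 3 == 0) time <- round(time, 1) + 0.01
    fit <- fit_cox(time, event, X)
    ref <- survival::coxph(survival::Surv(time, event) ~ X,
                           ties = "efron")
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(fit$se),
                 unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  }
})

test_that("Cox properties: convergence, translation invariance, null calibration, recovery", {
  set.seed(64)
  n <- 300
  x <- rnorm(n)
  tt <- rexp(n, exp(0.7 * x)); cc <- rexp(n, 0.2)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  fit <- fit_cox(time, event, cbind(x = x))
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-8 * max(1, abs(fit$loglik[["final"]])))
  ## translation invariance of the covariate
  fit_shift <- fit_cox(time, event, cbind(x = x + 100))
  expect_equal(fit$beta, fit_shift$beta, tolerance = 1e-6)

  ## type-I error near nominal under the null (scaled-down: 400 reps)
  set.seed(65)
  rej <- replicate(400, {
    m <- 60
    z <- rnorm(m)
    t2 <- rexp(m); c2 <- rexp(m, 0.3)
    f <- fit_cox(pmin(t2, c2), as.integer(t2 <= c2), cbind(z = z))
    f$p[1] < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.09)

  ## parameter recovery: true log-HR 0.7 at n = 500
  set.seed(66)
  betas <- replicate(20, {
    z <- rnorm(500)
    t2 <- rexp(500, exp(0.7 * z)); c2 <- rexp(500, 0.15)
    fit_cox(pmin(t2, c2), as.integer(t2 <= c2), cbind(z = z))$beta[[1]]
  })
  expect_equal(mean(betas), 0.7, tolerance = 0.07)

  ## guards
  expect_error(fit_cox(time, event, cbind(k = rep(1, n))), "constant")
  expect_error(fit_cox(time, rep(0, n), cbind(x = x)), "at least one event")
  ## monotone likelihood is flagged
  tm <- c(1, 2, 3, 4, 5, 6)
  xm <- c(1, 2, 3, 4, 5, 6)
  fm <- fit_cox(tm, rep(1, 6), cbind(x = xm))
  expect_true(length(fm$warnings) > 0)
})

test_that("Kaplan-Meier: no-censoring equivalence, all-censored, closed-form median", {
  ## no censoring: KM equals the empirical survival function exactly
  set.seed(67)
  tt <- sample(1:20, 50, replace = TRUE)
  km <- kaplan_meier(tt, rep(1, 50))
  for (k in seq_len(nrow(km)))
    expect_equal(km$survival[k], mean(tt > km$time[k]), tolerance = 1e-12)

  ## all censored: survival stays 1
  km1 <- kaplan_meier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km1$survival == 1))
  expect_true(is.na(attr(km1, "medians")[["all"]]))

  ## exponential samples of n = 2000: KM median within 5% of ln 2 / lambda
  ## (averaged over 5 replicates; a single sample sits ~1 sd from the 5%
  ## edge)
  set.seed(68)
  lam <- 0.8
  meds <- replicate(5, {
    tun <- rexp(2000, lam)
    attr(kaplan_meier(tun, rep(1, 2000)), "medians")[["all"]]
  })
  expect_equal(mean(meds), log(2) / lam, tolerance = 0.05)
  set.seed(168)
  tt2 <- rexp(2000, lam)
  cc2 <- rexp(2000, 0.1)
  km2 <- kaplan_meier(pmin(tt2, cc2), as.integer(tt2 <= cc2))

  ## agreement with the survival package on a censored sample
  skip_if_not_installed("survival")
  sf <- survival::survfit(survival::Surv(pmin(tt2, cc2),
                                         as.integer(tt2 <= cc2)) ~ 1)
  km_surv <- km2$survival
  expect_equal(km_surv, summary(sf, times = km2$time)$surv,
               tolerance = 1e-9)
})

test_that("hr_table: planted per-quartile hazard recovered, null FDR controlled, covariate guards", {
  ## planted per-quartile log-HR via a severity-free direct construction
  set.seed(69)
  n <- 500
  sev <- rnorm(n)
  marker <- exp(1.2 * sev + rnorm(n, sd = 0.4))
  q <- quartile_encode(log2(marker))
  tt <- rexp(n, 0.2 * exp(log(2) * q)); cc <- runif(n, 2, 5)
  tab <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc),
                    age = rnorm(n, 70, 8), weight = rnorm(n, 80, 10),
                    sex = sample(c("male", "female"), n, TRUE),
                    creatinine = exp(rnorm(n, 0.2, 0.2)),
                    vo2peak = rnorm(n, 14, 3), lvef = rnorm(n, 25, 8),
                    marker_001 = marker)
  hr <- hr_table(tab, "marker_001")
  expect_equal(hr$hr_crude, 2, tolerance = 0.1)
  expect_lt(hr$q_crude, 0.05)

  ## null: ~5% of crude q-values significant across 40 null markers
  set.seed(70)
  n2 <- 150
  nulltab <- data.frame(time = rexp(n2, 0.4), event = rbinom(n2, 1, 0.7),
                        age = rnorm(n2, 70, 8), weight = rnorm(n2, 80, 10),
                        sex = sample(c("male", "female"), n2, TRUE),
                        creatinine = exp(rnorm(n2, 0.2, 0.2)),
                        vo2peak = rnorm(n2, 14, 3), lvef = rnorm(n2, 25, 8))
  mk <- matrix(exp(rnorm(n2 * 40)), n2, 40,
               dimnames = list(NULL, sprintf("marker_%03d", 1:40)))
  nulltab <- cbind(nulltab, mk)
  hr0 <- hr_table(nulltab, colnames(mk))
  expect_lte(mean(hr0$q_crude < 0.05), 0.05)
  expect_true(all(hr0$q_crude >= hr0$p_crude))

  expect_error(hr_table(tab[, setdiff(names(tab), "lvef")], "marker_001"),
               "lvef")
})

test_that("adjustment attenuates a marker that proxies an included covariate", {
  set.seed(71)
  n <- 600
  lvef <- rnorm(n, 25, 8)
  ## hazard depends on LVEF only; the marker is a noisy proxy of LVEF
  marker <- exp(-0.1 * lvef + rnorm(n, sd = 0.3))
  tt <- rexp(n, 0.05 * exp(-0.08 * (lvef - 25)))
  cc <- runif(n, 2, 5)
  tab <- data.frame(time = pmin(tt, cc), event = as.integer(tt <= cc),
                    age = rnorm(n, 70, 8), weight = rnorm(n, 80, 10),
                    sex = sample(c("male", "female"), n, TRUE),
                    creatinine = exp(rnorm(n, 0.2, 0.2)),
                    vo2peak = rnorm(n, 14, 3), lvef = lvef,
                    marker_001 = marker)
  hr <- hr_table(tab, "marker_001")
  expect_gt(hr$hr_crude, 1.2)
  expect_lt(abs(log(hr$hr_adj)), abs(log(hr$hr_crude)))
})

test_that("pc_risk: null scores give HR ~ 1; severity-linked cohort shows quadrant gradient", {
  set.seed(72)
  n <- 400
  tt <- rexp(n, 0.3); cc <- runif(n, 2, 5)
  time <- pmin(tt, cc); event <- as.integer(tt <= cc)
  pr0 <- pc_risk(rnorm(n), rnorm(n), time, event)
  expect_lt(max(abs(log(pr0$axis$hr))), 0.45)

  ## deterministic on a fixed cohort
  pr0b <- pc_risk_input <- NULL
  s1 <- rnorm(n); s2 <- rnorm(n)
  a <- pc_risk(s1, s2, time, event)
  b <- pc_risk(s1, s2, time, event)
  expect_identical(a$axis, b$axis)

  ## strong-coupling cohort: LL vs UR HR exceeds 1 with CI excluding 1
  cfg <- strong_coupling_config(n_hf = 500, seed = 78)
  coh <- simulate_cohort(cfg)
  spec <- default_physiology_spec()
  comb <- fit_pca(as.matrix(coh$table[, spec$variable[spec$in_combined]]))
  orient <- default_orientation()[rownames(comb$loadings)]
  sc <- comb$scores[, 1:2]
  for (k in 1:2)
    if (sum(comb$loadings[, k] * orient) < 0) sc[, k] <- -sc[, k]
  pr <- pc_risk(sc[, 1], sc[, 2], coh$table$time, coh$table$event)
  ll <- pr$quadrant[pr$quadrant$contrast == "LL_vs_UR", ]
  expect_gt(ll$hr, 1)
  expect_gt(ll$lo, 1)
  ## worst-vs-best quadrant HR above both single-axis HRs
  expect_gt(ll$hr, max(pr$axis$hr))
})
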