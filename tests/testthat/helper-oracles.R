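## Independent oracles used across the suite. These are deliberately
## written from the textbook definitions (elementary loops, no shared code
## with the package implementations they check).

## brute-force binned mutual information: same estimator definition
## (stable ranks -> equal-frequency bins), joint/marginal probabilities via
## explicit double loop over the contingency table
oracle_mi <- function(x, y, bins) {
  n <- length(x)
  rank_first <- function(v) order(order(v))   # stable competition ranks
  bx <- floor((rank_first(x) - 1) * bins / n)
  by <- floor((rank_first(y) - 1) * bins / n)
  mi <- 0
  for (a in 0:(bins - 1)) {
    for (b2 in 0:(bins - 1)) {
      pj <- sum(bx == a & by == b2) / n
      if (pj > 0) {
        px <- sum(bx == a) / n
        py <- sum(by == b2) / n
        mi <- mi + pj * log(pj / (px * py))
      }
    }
  }
  mi
}

## Efron partial log-likelihood for a single covariate, direct definition
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (et in unique(time[event == 1])) {
    dset <- which(time == et & event == 1)
    risk <- which(time >= et)
    d <- length(dset)
    sum_d <- sum(exp(beta * x[dset]))
    sum_r <- sum(exp(beta * x[risk]))
    ll <- ll + beta * sum(x[dset])
    for (l in seq_len(d) - 1) {
      ll <- ll - log(sum_r - (l / d) * sum_d)
    }
  }
  ll
}

oracle_cox_beta <- function(time, event, x, lower = -20, upper = 20) {
  opt <- optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-10)
  opt$maximum
}

## textbook O-PLS (Trygg & Wold conventions; normalisations differ from the
## package implementation, so fitted values and R2Y are compared)
oracle_opls <- function(X, y, n_orth) {
  X <- scale(X)
  u <- y - mean(y)
  Xd <- X
  for (j in seq_len(n_orth)) {
    w <- drop(crossprod(Xd, u)) / sum(u^2)
    w <- w / sqrt(sum(w^2))
    t_s <- drop(Xd %*% w) / sum(w^2)
    p <- drop(crossprod(Xd, t_s)) / sum(t_s^2)
    w_o <- p - (sum(w * p) / sum(w^2)) * w
    if (sqrt(sum(w_o^2)) < 1e-12) break
    w_o <- w_o / sqrt(sum(w_o^2))
    t_o <- drop(Xd %*% w_o) / sum(w_o^2)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
  }
  w <- drop(crossprod(Xd, u)) / sum(u^2)
  w <- w / sqrt(sum(w^2))
  t_s <- drop(Xd %*% w)
  b <- sum(t_s * u) / sum(t_s^2)
  yhat <- b * t_s
  list(w = w, yhat = yhat, r2y = 1 - sum((u - yhat)^2) / sum(u^2))
}

## small default cohort cached per test session (simulation is cheap but
## used by several files)
default_cohort_cached <- local({
  coh <- NULL
  function() {
    if (is.null(coh)) coh <<- simulate_cohort(cohort_config(seed = 20260911))
    coh
  }
})

## strong-coupling scenario: severity_link scaled up relative to the
## calibrated default; used for latent-severity recovery by PC scores and
## for quadrant-risk power (a scenario definition, not the default world)
strong_coupling_config <- function(n_hf = 500, seed = 1) {
  cohort_config(
    n_hf = n_hf, n_ctrl = 0,
    severity_coupling = c(physical_capacity = 0.9, daily_activity = 0.9,
                          myocardial_function = 0.54),
    seed = seed)
}

## network-recovery scenario: 20 direct marker-category dependencies
## (7 capacity, 7 activity, 6 myocardial spokes), marker severity loadings
## switched off so the planted star edges are the only marker-category
## structure; clusters are interleaved within each category so that
## same-category marker pairs are mostly cross-cluster
recovery_config <- function(n_hf = 500, seed = 1, loading = 1.6) {
  panel <- default_marker_panel()
  panel$severity_loading[] <- 0
  by_cluster <- split(panel$column, panel$cluster)
  interleave <- as.vector(t(vapply(by_cluster, function(x) x[1:7],
                                   character(7))))
  targets <- interleave[1:20]
  mcl <- data.frame(
    column = targets,
    category = rep(c("physical_capacity", "daily_activity",
                     "myocardial_function"), c(7, 7, 6)),
    loading = loading, stringsAsFactors = FALSE)
  cohort_config(n_hf = n_hf, n_ctrl = 0, marker_panel = panel,
                marker_category_loading = mcl, seed = seed)
}

## (marker, category) links detected by a connectivity report, as
## "marker category" strings
detected_links <- function(conn) {
  det <- conn$factors
  unlist(lapply(seq_len(nrow(det)), function(i) {
    if (!nzchar(det$categories[i])) return(character(0))
    paste(det$factor[i], strsplit(det$categories[i], ";")[[1]])
  }))
}
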