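## Cox proportional hazards (Newton-Raphson, Efron ties), per-quartile
## hazard-ratio tables, Kaplan-Meier estimation and PC/quadrant risk.

#' Quartile coding of a marker
#'
#' Ordinal quartile membership (1-4) using type-7 (linear interpolation)
#' quantiles; values exactly at a quartile boundary go to the lower
#' quartile. Rank-based, hence invariant to strictly monotone transforms
#' such as log2.
#'
#' @param values Numeric vector with at least 4 distinct values.
#' @return Integer vector of codes 1-4.
#' @export
#' @examples
#' quartile_encode(1:8)  # 1 1 2 2 3 3 4 4
quartile_encode <- function(values) {
  if (length(unique(values)) < 4)
    stop("need at least 4 distinct values to form quartiles")
  qs <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  1L + (values > qs[1]) + (values > qs[2]) + (values > qs[3])
}

#' Fit a Cox proportional-hazards model
#'
#' Newton-Raphson maximisation of the partial likelihood with Efron's
#' approximation for tied event times; step-halving when a step decreases
#' the log-likelihood; convergence when the largest coefficient update is
#' below `tol`. Standard errors come from the inverse observed
#' information. Monotone (divergent) likelihoods -- e.g. a covariate that
#' perfectly separates risk sets -- are flagged via `warnings` rather than
#' silently returned.
#'
#' @param time Follow-up times (> 0).
#' @param event Event indicator (0/1), at least one event.
#' @param covariates Numeric matrix or data.frame of covariates; no
#'   constant columns.
#' @param max_iter,tol Newton-Raphson controls.
#' @return Object of class `cox_fit`: `beta`, `se`, `hr` (with `hr_lo`,
#'   `hr_hi`), `z`, `p`, `loglik` (null and final), `iterations`,
#'   `converged`, `warnings`.
#' @export
fit_cox <- function(time, event, covariates, max_iter = 50, tol = 1e-9) {
  X <- as.matrix(covariates)
  storage.mode(X) <- "double"
  n <- length(time)
  if (nrow(X) != n || length(event) != n)
    stop("time, event and covariates must align")
  if (any(!is.finite(X))) stop("covariates must be finite")
  if (any(time <= 0)) stop("times must be positive")
  if (sum(event) < 1) stop("need at least one event")
  const <- apply(X, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    stop("constant covariate(s): ",
         paste(colnames(X)[const], collapse = ", "))
  p <- ncol(X)
  ord <- order(time)
  X <- X[ord, , drop = FALSE]
  tt <- time[ord]; ev <- event[ord]
  ## unique event times and tie groups
  etimes <- unique(tt[ev == 1])
  loglik_grad_info <- function(beta) {
    eta <- drop(X %*% beta)
    ex <- exp(eta)
    ll <- 0
    grad <- numeric(p)
    info <- matrix(0, p, p)
    for (et in etimes) {
      risk <- which(tt >= et)
      dset <- which(tt == et & ev == 1)
      d <- length(dset)
      s0_r <- sum(ex[risk])
      s1_r <- colSums(X[risk, , drop = FALSE] * ex[risk])
      s2_r <- crossprod(X[risk, , drop = FALSE] * sqrt(ex[risk]))
      s0_d <- sum(ex[dset])
      s1_d <- colSums(X[dset, , drop = FALSE] * ex[dset])
      s2_d <- crossprod(X[dset, , drop = FALSE] * sqrt(ex[dset]))
      ll <- ll + sum(eta[dset])
      grad <- grad + colSums(X[dset, , drop = FALSE])
      for (l in seq_len(d) - 1) {
        f <- l / d
        s0 <- s0_r - f * s0_d
        s1 <- s1_r - f * s1_d
        s2 <- s2_r - f * s2_d
        ll <- ll - log(s0)
        grad <- grad - s1 / s0
        info <- info + s2 / s0 - tcrossprod(s1 / s0)
      }
    }
    list(ll = ll, grad = grad, info = info)
  }
  beta <- numeric(p)
  cur <- loglik_grad_info(beta)
  ll0 <- cur$ll
  converged <- FALSE
  warnings_out <- character(0)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    step <- tryCatch(solve(cur$info, cur$grad), error = function(e) NULL)
    if (is.null(step)) {
      warnings_out <- c(warnings_out, "singular information matrix")
      break
    }
    new_beta <- beta + step
    new <- loglik_grad_info(new_beta)
    halvings <- 0L
    while ((!is.finite(new$ll) || new$ll < cur$ll) && halvings < 20L) {
      step <- step / 2
      new_beta <- beta + step
      new <- loglik_grad_info(new_beta)
      halvings <- halvings + 1L
    }
    delta <- max(abs(new_beta - beta))
    beta <- new_beta
    cur <- new
    ## converged when the update stalls and the score is numerically zero
    ## relative to the log-likelihood scale
    if (delta < tol &&
        sqrt(sum(cur$grad^2)) < 1e-8 * max(1, abs(cur$ll))) {
      converged <- TRUE
      break
    }
  }
  if (!converged && iter >= max_iter)
    warnings_out <- c(warnings_out, "maximum iterations reached")
  if (any(abs(beta) > 15))
    warnings_out <- c(warnings_out,
                      "monotone likelihood suspected (diverging coefficient)")
  vcv <- tryCatch(solve(cur$info), error = function(e)
    matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vcv), 0))
  z <- beta / se
  nm <- colnames(X) %||% paste0("x", seq_len(p))
  structure(list(beta = setNames(beta, nm), se = setNames(se, nm),
                 hr = setNames(exp(beta), nm),
                 hr_lo = setNames(exp(beta - 1.96 * se), nm),
                 hr_hi = setNames(exp(beta + 1.96 * se), nm),
                 z = z, p = 2 * pnorm(-abs(z)),
                 loglik = c(null = ll0, final = cur$ll),
                 score_norm = sqrt(sum(cur$grad^2)),
                 iterations = iter, converged = converged,
                 warnings = warnings_out, vcov = vcv),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  tab <- data.frame(beta = x$beta, se = x$se, HR = x$hr,
                    lo95 = x$hr_lo, hi95 = x$hr_hi, p = x$p)
  print(round(tab, 4))
  if (length(x$warnings)) cat("warnings:", x$warnings, "\n")
  invisible(x)
}

#' Per-marker hazard-ratio table (crude and adjusted)
#'
#' Mirrors the per-quartile analysis: each marker is log2-transformed,
#' quartile-coded (1-4, entered as a linear ordinal term) and fitted
#' crude (marker alone) and adjusted for a covariate set. The default
#' adjustment set is age, estimated creatinine clearance (Cockcroft-Gault),
#' peak VO2 and LVEF; the alternative set is age, sex and log2 NT-proBNP.
#' BH-FDR is applied across markers within each model family.
#'
#' @param table Cohort data frame (needs `time`, `event`, and the
#'   adjustment covariates).
#' @param marker_cols Marker columns to analyse.
#' @param adjust `"renal_function"` (age, eGFR, VO2peak, LVEF) or
#'   `"neurohormonal"` (age, sex, NT-proBNP).
#' @param ntprobnp_col Column holding NT-proBNP abundances (used by the
#'   neurohormonal set).
#' @return Data frame of class `hr_table`: per marker, crude and adjusted
#'   HR / p / q and the covariate set used.
#' @export
hr_table <- function(table, marker_cols,
                     adjust = c("renal_function", "neurohormonal"),
                     ntprobnp_col = NULL) {
  adjust <- match.arg(adjust)
  need_base <- c("time", "event")
  if (adjust == "renal_function") {
    need <- c(need_base, "age", "weight", "sex", "creatinine",
              "vo2peak", "lvef")
  } else {
    need <- c(need_base, "age", "sex")
    if (is.null(ntprobnp_col))
      stop("neurohormonal adjustment needs ntprobnp_col")
    need <- c(need, ntprobnp_col)
  }
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  if (adjust == "renal_function") {
    adj <- data.frame(
      age = table$age,
      egfr = cockcroft_gault(table$age, table$weight, table$sex,
                             table$creatinine),
      vo2peak = table$vo2peak, lvef = table$lvef)
  } else {
    adj <- data.frame(
      age = table$age,
      sex_male = as.numeric(table$sex == "male"),
      log2_ntprobnp = log2(table[[ntprobnp_col]]))
  }
  rows <- lapply(marker_cols, function(mk) {
    qcode <- quartile_encode(log2(table[[mk]]))
    crude <- fit_cox(table$time, table$event,
                     matrix(qcode, ncol = 1,
                            dimnames = list(NULL, "quartile")))
    adj_fit <- tryCatch(
      fit_cox(table$time, table$event, cbind(quartile = qcode, adj)),
      error = function(e) NULL)
    data.frame(marker = mk,
               hr_crude = crude$hr[["quartile"]],
               p_crude = crude$p[[1]],
               hr_adj = if (is.null(adj_fit)) NA_real_ else
                 adj_fit$hr[["quartile"]],
               p_adj = if (is.null(adj_fit)) NA_real_ else
                 adj_fit$p[[which(names(adj_fit$beta) == "quartile")]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_crude <- bh_fdr(out$p_crude)
  ok <- !is.na(out$p_adj)
  out$q_adj <- NA_real_
  if (any(ok)) out$q_adj[ok] <- bh_fdr(out$p_adj[ok])
  out$adjustment <- adjust
  class(out) <- c("hr_table", "data.frame")
  out
}

#' Kaplan-Meier estimator
#'
#' Product-limit survival estimate per group with Greenwood standard
#' errors, pointwise 95% confidence bands and median survival.
#'
#' @param time Follow-up times.
#' @param event Event indicator (0/1).
#' @param groups Optional grouping vector (default: one group).
#' @return Data frame of class `km_fit` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`, `se`, `ci_lo`, `ci_hi`;
#'   attribute `medians` holds per-group median survival.
#' @export
kaplan_meier <- function(time, event, groups = NULL) {
  if (is.null(groups)) groups <- rep("all", length(time))
  g <- as.character(groups)
  out <- list(); med <- c()
  for (lv in unique(g)) {
    tt <- time[g == lv]; ev <- event[g == lv]
    if (!length(tt)) next
    ut <- sort(unique(tt))
    n_risk <- vapply(ut, function(u) sum(tt >= u), numeric(1))
    n_event <- vapply(ut, function(u) sum(tt == u & ev == 1), numeric(1))
    n_cens <- vapply(ut, function(u) sum(tt == u & ev == 0), numeric(1))
    surv <- cumprod(1 - n_event / n_risk)
    gw <- cumsum(ifelse(n_event > 0,
                        n_event / (n_risk * (n_risk - n_event)), 0))
    se <- surv * sqrt(gw)
    lo <- pmax(surv - 1.96 * se, 0)
    hi <- pmin(surv + 1.96 * se, 1)
    med_lv <- if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_
    med[lv] <- med_lv
    out[[lv]] <- data.frame(group = lv, time = ut, n_risk = n_risk,
                            n_event = n_event, n_censor = n_cens,
                            survival = surv, se = se,
                            ci_lo = lo, ci_hi = hi,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "medians") <- med
  class(res) <- c("km_fit", "data.frame")
  res
}

#' PC-score and quadrant hazard ratios
#'
#' Hazard ratios for below-median (worse-function) PC1 and PC2 scores and
#' for quadrant contrasts against the best-function quadrant (`UR`).
#' Quadrant contrasts with an empty or event-free group are dropped with a
#' warning.
#'
#' @param pc1,pc2 Score vectors oriented so that higher = better function.
#' @param time,event Survival outcome.
#' @return List of class `pc_risk`: `axis` (data frame: HR, CI, p for low
#'   PC1 and low PC2), `quadrant` (data frame: HR of each quadrant vs UR),
#'   `groups` (the quadrant labels).
#' @export
pc_risk <- function(pc1, pc2, time, event) {
  qg <- quadrant_groups(pc1, pc2)
  ax <- lapply(list(low_pc1 = qg$low_pc1, low_pc2 = qg$low_pc2),
               function(ind) {
                 f <- fit_cox(time, event,
                              matrix(as.numeric(ind), ncol = 1,
                                     dimnames = list(NULL, "low")))
                 c(hr = f$hr[[1]], lo = f$hr_lo[[1]], hi = f$hr_hi[[1]],
                   p = f$p[[1]])
               })
  axis_df <- data.frame(contrast = names(ax), do.call(rbind, ax),
                        stringsAsFactors = FALSE)
  quad <- qg$quadrant
  rows <- list()
  for (lv in c("LL", "LR", "UL")) {
    sel <- quad %in% c(lv, "UR")
    if (!sum(quad == lv) || !sum(quad == "UR") ||
        sum(event[sel]) == 0) {
      warning("quadrant contrast ", lv, " vs UR dropped (empty group ",
              "or no events)")
      next
    }
    f <- tryCatch(
      fit_cox(time[sel], event[sel],
              matrix(as.numeric(quad[sel] == lv), ncol = 1,
                     dimnames = list(NULL, lv))),
      error = function(e) NULL)
    if (is.null(f)) next
    rows[[lv]] <- data.frame(contrast = paste0(lv, "_vs_UR"),
                             hr = f$hr[[1]], lo = f$hr_lo[[1]],
                             hi = f$hr_hi[[1]], p = f$p[[1]],
                             stringsAsFactors = FALSE)
  }
  structure(list(axis = axis_df,
                 quadrant = do.call(rbind, rows),
                 groups = quad), class = "pc_risk")
}
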