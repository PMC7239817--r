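## Two-class orthogonal projections to latent structures discriminant
## analysis (OPLS-DA), implemented from first principles: one predictive
## component plus a configurable number of response-orthogonal components,
## cross-validated Q2, VIP scores, and bootstrap loading intervals.

code_response <- function(y) {
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2)
    stop("OPLS-DA requires exactly two classes, got ", length(lev))
  yc <- ifelse(as.character(y) == lev[2], 1, -1)
  list(y = yc - mean(yc), raw = yc, levels = lev)
}

#' Fit a two-class OPLS-DA model
#'
#' Columns of `X` are mean-centred and scaled to unit variance; the class
#' response is coded -1/+1 and mean-centred. The algorithm alternates: the
#' predictive weight `w` is proportional to `X'y`; for each orthogonal
#' component the loading `p` of `X` on the current predictive score is
#' split into its `w`-parallel and `w`-orthogonal parts, the orthogonal
#' part defines an orthogonal score that is deflated from `X`; the final
#' predictive component is extracted from the deflated matrix. `R2Y` is the
#' fraction of response variance explained by the regression of `y` on the
#' predictive score.
#'
#' @param X Numeric matrix (subjects x variables).
#' @param y Two-class vector.
#' @param n_orth Number of orthogonal components (>= 0).
#' @param scale. Scale columns to unit variance (default TRUE).
#' @return Object of class `opls_model`: predictive weight `w` (unit norm),
#'   loading `p_load`, scores `t`, orthogonal `W_orth`/`P_orth`/`T_orth`,
#'   regression scalar `b`, `r2y`, training accuracy, scaling parameters
#'   and class coding.
#' @export
fit_opls <- function(X, y, n_orth = 1, scale. = TRUE) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("X and y dimensions disagree")
  cod <- code_response(y)
  if (nrow(X) <= n_orth + 1)
    stop("need more subjects than n_orth + 1")
  if (n_orth >= min(dim(X)))
    stop("n_orth exceeds the rank limit of X")
  ctr <- colMeans(X)
  scl <- if (scale.) apply(X, 2, sd) else rep(1, ncol(X))
  if (any(scl == 0)) stop("zero-variance column(s) in X")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  yc <- cod$y
  Xd <- Xs
  W_orth <- P_orth <- NULL
  T_orth <- NULL
  k_done <- 0L
  for (k in seq_len(n_orth)) {
    w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
    t_p <- drop(Xd %*% w)
    p <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
    w_o <- p - sum(w * p) * w
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-12) break         # no orthogonal variation left
    w_o <- w_o / nrm
    t_o <- drop(Xd %*% w_o)
    p_o <- drop(crossprod(Xd, t_o)) / sum(t_o^2)
    Xd <- Xd - tcrossprod(t_o, p_o)
    W_orth <- cbind(W_orth, w_o)
    P_orth <- cbind(P_orth, p_o)
    T_orth <- cbind(T_orth, t_o)
    k_done <- k
  }
  w <- drop(crossprod(Xd, yc)); w <- w / sqrt(sum(w^2))
  t_p <- drop(Xd %*% w)
  p_load <- drop(crossprod(Xd, t_p)) / sum(t_p^2)
  b <- sum(t_p * yc) / sum(t_p^2)
  resid <- yc - b * t_p
  r2y <- 1 - sum(resid^2) / sum(yc^2)
  fitted_class <- ifelse(b * t_p >= 0, cod$levels[2], cod$levels[1])
  model <- structure(list(
    w = w, p_load = p_load, t = t_p, b = b,
    n_orth = k_done, W_orth = W_orth, P_orth = P_orth, T_orth = T_orth,
    r2y = r2y, center = ctr, scale = scl, levels = cod$levels,
    accuracy = mean(fitted_class == as.character(y)),
    K = ncol(X)), class = "opls_model")
  model
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "opls_model: %d variables, %d orthogonal component(s), R2Y = %.3f, accuracy = %.3f\n",
    x$K, x$n_orth, x$r2y, x$accuracy))
  invisible(x)
}

#' Predict classes with a fitted OPLS-DA model
#'
#' New data are scaled with the training parameters, orthogonal components
#' are deflated, and the predictive score is thresholded at the class-code
#' midpoint (zero).
#'
#' @param object An `opls_model`.
#' @param newdata Matrix with the training variables.
#' @param ... Unused.
#' @return List: `score` (numeric), `class` (character), `yhat` (regression
#'   prediction on the coded scale).
#' @export
predict.opls_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$K)
    stop("newdata has ", ncol(newdata), " variables; model expects ",
         object$K)
  Xs <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  if (object$n_orth > 0) {
    for (k in seq_len(object$n_orth)) {
      t_o <- drop(Xs %*% object$W_orth[, k])
      Xs <- Xs - tcrossprod(t_o, object$P_orth[, k])
    }
  }
  t_new <- drop(Xs %*% object$w)
  yhat <- object$b * t_new
  list(score = t_new, yhat = yhat,
       class = ifelse(yhat >= 0, object$levels[2], object$levels[1]))
}

#' Classify observations and report accuracy
#'
#' @param model An `opls_model`.
#' @param X Data matrix on the original (unscaled) variable scale.
#' @param truth Optional true class labels.
#' @return List: `class`, and `accuracy` when `truth` is given.
#' @export
classify_opls <- function(model, X, truth = NULL) {
  pr <- predict(model, X)
  out <- list(class = pr$class)
  if (!is.null(truth))
    out$accuracy <- mean(pr$class == as.character(truth))
  out
}

#' Cross-validated Q2 with orthogonal-component selection
#'
#' Stratified k-fold cross-validation:
#' `Q2 = 1 - PRESS / SS` over held-out folds, where scaling and model
#' fitting use the training folds only. The number of orthogonal
#' components is grown from 0 while Q2 improves by more than `delta`
#' (default 0.01), up to `max_orth`.
#'
#' @param X Data matrix.
#' @param y Two-class vector.
#' @param folds Number of folds (default 7).
#' @param max_orth Maximum orthogonal components tried.
#' @param delta Minimum Q2 improvement to accept a further component.
#' @param seed Optional seed for the fold assignment.
#' @return List: `q2` (at the chosen size), `n_orth`, `q2_path`.
#' @export
opls_cv <- function(X, y, folds = 7, max_orth = 3, delta = 0.01,
                    seed = NULL) {
  X <- as.matrix(X)
  if (!is.null(seed)) set.seed(seed)
  cod <- code_response(y)
  cls <- as.character(y)
  ## stratified fold assignment
  fold_id <- integer(length(y))
  for (lv in cod$levels) {
    idx <- which(cls == lv)
    if (length(idx) < folds && length(idx) < 2)
      stop("a class has fewer than 2 members; cannot stratify folds")
    fold_id[idx] <- sample(rep(seq_len(folds),
                               length.out = length(idx)))
  }
  q2_for <- function(n_orth) {
    press <- 0; ss <- 0
    for (f in seq_len(folds)) {
      tr <- fold_id != f; te <- !tr
      if (!any(te)) next
      if (length(unique(cls[tr])) < 2)
        stop("a training fold lost a class; reduce the fold count")
      m <- fit_opls(X[tr, , drop = FALSE], y[tr], n_orth = n_orth)
      ytr <- ifelse(cls[tr] == cod$levels[2], 1, -1)
      yte <- ifelse(cls[te] == cod$levels[2], 1, -1) - mean(ytr)
      pr <- predict(m, X[te, , drop = FALSE])
      press <- press + sum((yte - pr$yhat)^2)
      ss <- ss + sum(yte^2)
    }
    1 - press / ss
  }
  path <- q2_for(0)
  n_sel <- 0L
  for (k in seq_len(max_orth)) {
    q2k <- q2_for(k)
    path <- c(path, q2k)
    if (q2k - path[n_sel + 1L] > delta) n_sel <- k else break
  }
  list(q2 = path[n_sel + 1L], n_orth = n_sel, q2_path = path)
}

#' Variable importance in projection
#'
#' For a single predictive component the VIP reduces to
#' `sqrt(K) * |w_j|` with `w` unit-norm, so that the squared VIPs always
#' sum to the number of variables.
#'
#' @param model A fitted `opls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
opls_vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("model must be an opls_model")
  vip <- sqrt(model$K) * abs(model$w)
  names(vip) <- names(model$w)
  vip
}

#' Bootstrap significance of variable contributions
#'
#' Resamples subjects with replacement, refits the model, aligns each
#' replicate's predictive loading sign to the point estimate (latent
#' components have a sign indeterminacy), and returns percentile 95%
#' confidence intervals for each variable's predictive loading; a variable
#' is flagged significant when its interval excludes zero. Degenerate
#' resamples containing one class are redrawn.
#'
#' @param X Data matrix.
#' @param y Two-class vector.
#' @param B Number of bootstrap replicates (>= 200).
#' @param n_orth Orthogonal components per refit.
#' @param seed Optional RNG seed.
#' @param conf Confidence level.
#' @return Data frame: `variable`, `loading`, `lo`, `hi`, `significant`.
#' @export
opls_bootstrap <- function(X, y, B = 1000, n_orth = 1, seed = NULL,
                           conf = 0.95) {
  if (B < 200) stop("B must be at least 200")
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- nrow(X)
  base <- fit_opls(X, y, n_orth = n_orth)
  cls <- as.character(y)
  boots <- matrix(NA_real_, B, ncol(X))
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(cls[idx])) == 2) break
    }
    m <- tryCatch(fit_opls(X[idx, , drop = FALSE], y[idx],
                           n_orth = n_orth),
                  error = function(e) NULL)
    if (is.null(m)) next
    pl <- m$p_load
    if (sum(pl * base$p_load) < 0) pl <- -pl
    boots[b, ] <- pl
  }
  a <- (1 - conf) / 2
  lo <- apply(boots, 2, quantile, probs = a, na.rm = TRUE)
  hi <- apply(boots, 2, quantile, probs = 1 - a, na.rm = TRUE)
  data.frame(variable = colnames(X) %||% paste0("V", seq_len(ncol(X))),
             loading = base$p_load, lo = lo, hi = hi,
             significant = lo > 0 | hi < 0,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
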