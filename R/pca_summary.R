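## Principal-component summary scores for clinical variable blocks, and the
## quadrant risk grouping used for survival stratification.

#' Principal components of scaled data
#'
#' Eigen-decomposition of the correlation matrix of the (unit-variance
#' scaled, mean-centred) data. Component signs follow a deterministic
#' convention: the element of largest absolute loading is made positive.
#'
#' @param X Numeric matrix (subjects x variables, >= 2 variables).
#' @param n_comp Number of components to retain (default: all).
#' @return Object of class `pca_summary`: `loadings` (orthonormal columns),
#'   `scores` (= scaled data times loadings), `var_ratio` (non-increasing,
#'   sums to 1 over all components), `sdev`, `center`, `scale_`.
#' @export
fit_pca <- function(X, n_comp = NULL) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 variables")
  sds <- apply(X, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  Xs <- scale(X)
  R <- cor(X)
  ee <- eigen(R, symmetric = TRUE)
  p <- ncol(X)
  if (is.null(n_comp)) n_comp <- p
  n_comp <- min(n_comp, p)
  L <- ee$vectors
  ## deterministic sign: largest-|loading| element positive
  for (k in seq_len(p)) {
    j <- which.max(abs(L[, k]))
    if (L[j, k] < 0) L[, k] <- -L[, k]
  }
  vr <- ee$values / sum(ee$values)
  scores <- Xs %*% L
  colnames(L) <- colnames(scores) <- paste0("PC", seq_len(p))
  rownames(L) <- colnames(X)
  structure(list(loadings = L[, seq_len(n_comp), drop = FALSE],
                 scores = scores[, seq_len(n_comp), drop = FALSE],
                 var_ratio = vr,
                 sdev = sqrt(pmax(ee$values, 0)),
                 center = attr(Xs, "scaled:center"),
                 scale_ = attr(Xs, "scaled:scale")),
            class = "pca_summary")
}

#' @export
print.pca_summary <- function(x, ...) {
  cat("pca_summary:", nrow(x$loadings), "variables;",
      "top-3 variance share",
      sprintf("%.3f", sum(x$var_ratio[seq_len(min(3, length(x$var_ratio)))])),
      "\n")
  invisible(x)
}

#' Category summary scores (PC1/PC2 per clinical block)
#'
#' Runs a PCA within each clinical category (physical capacity, daily
#' physical activity, myocardial function) and returns the first two
#' component scores per category, oriented so that a higher score means
#' better function: each component is flipped, if necessary, so that the
#' orientation-weighted sum of its loadings is positive (e.g. positive on
#' peak VO2, percent active, LVEF).
#'
#' @param table Cohort data frame containing the physiology columns.
#' @param category_map Named list mapping category names to column names
#'   (default [default_category_map()]). Every mapped variable must be
#'   present; a variable mapped to more than one category is an error.
#' @param orientation Named +1/-1 vector per variable (default
#'   [default_orientation()]).
#' @return List of class `category_scores`: `scores` (data frame with
#'   columns `<category>_PC1/PC2`), `fits` (per-category `pca_summary`),
#'   `category_map`.
#' @export
category_scores <- function(table, category_map = default_category_map(),
                            orientation = default_orientation()) {
  all_vars <- unlist(category_map, use.names = FALSE)
  if (anyDuplicated(all_vars))
    stop("variable(s) assigned to more than one category: ",
         paste(unique(all_vars[duplicated(all_vars)]), collapse = ", "))
  missing_cols <- setdiff(all_vars, names(table))
  if (length(missing_cols))
    stop("variable(s) missing from the table: ",
         paste(missing_cols, collapse = ", "))
  short <- vapply(category_map, length, integer(1)) < 2
  if (any(short))
    stop("category with fewer than 2 variables: ",
         paste(names(category_map)[short], collapse = ", "))
  fits <- list()
  out <- list()
  for (cat_name in names(category_map)) {
    vars <- category_map[[cat_name]]
    fit <- fit_pca(as.matrix(table[, vars, drop = FALSE]), n_comp = 2)
    orient <- orientation[vars]
    orient[is.na(orient)] <- 1
    for (k in 1:2) {
      if (sum(fit$loadings[, k] * orient) < 0) {
        fit$loadings[, k] <- -fit$loadings[, k]
        fit$scores[, k] <- -fit$scores[, k]
      }
    }
    fits[[cat_name]] <- fit
    out[[paste0(cat_name, "_PC1")]] <- fit$scores[, 1]
    out[[paste0(cat_name, "_PC2")]] <- fit$scores[, 2]
  }
  structure(list(scores = as.data.frame(out), fits = fits,
                 category_map = category_map),
            class = "category_scores")
}

#' Quadrant risk groups from two PC score vectors
#'
#' Median-splits each axis and labels subjects `LL`, `LR`, `UL`, `UR`
#' (lower/upper on the second axis, left/right on the first). With both
#' axes oriented so that a higher score means better function, `LL` is the
#' worst-function quadrant and `UR` the best. Also returns the single-axis
#' high/low indicators used for per-component hazard ratios.
#'
#' @param pc1_scores,pc2_scores Equal-length numeric score vectors.
#' @return List: `quadrant` (factor LL/LR/UL/UR), `low_pc1`, `low_pc2`
#'   (logical; below-median = worse function), `medians`.
#' @export
quadrant_groups <- function(pc1_scores, pc2_scores) {
  if (length(pc1_scores) != length(pc2_scores))
    stop("score vectors must have equal length")
  m1 <- median(pc1_scores); m2 <- median(pc2_scores)
  low1 <- pc1_scores < m1
  low2 <- pc2_scores < m2
  quad <- paste0(ifelse(low2, "L", "U"), ifelse(low1, "L", "R"))
  list(quadrant = factor(quad, levels = c("LL", "LR", "UL", "UR")),
       low_pc1 = low1, low_pc2 = low2, medians = c(pc1 = m1, pc2 = m2))
}
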