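## Shared statistics: scaling, renal function, method agreement, univariate
## screening, FDR control, correlation structure, cohort description.

#' Scale columns to zero mean and unit variance
#'
#' @param x Numeric matrix or data frame of numeric columns.
#' @return Matrix with each column mean-centred and scaled to sample SD 1.
#'   Errors on a zero-variance column, naming it.
#' @export
scale_unit_variance <- function(x) {
  x <- as.matrix(x)
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | is.na(sds))) {
    bad <- colnames(x)[which(sds == 0 | is.na(sds))]
    if (is.null(bad) || !length(bad)) bad <- which(sds == 0 | is.na(sds))
    stop("zero-variance column(s): ", paste(bad, collapse = ", "))
  }
  scale(x)[, , drop = FALSE]
}

#' Cockcroft-Gault creatinine clearance
#'
#' `CrCl = (140 - age) * weight / (72 * creatinine)`, multiplied by 0.85
#' for women. Units: years, kg, mg/dL; result in mL/min.
#'
#' @param age_y Age in years (< 140).
#' @param weight_kg Body weight in kg.
#' @param sex `"male"` or `"female"` (vectorised).
#' @param creatinine_mg_dl Serum creatinine in mg/dL (> 0).
#' @return Creatinine clearance in mL/min.
#' @export
#' @examples
#' cockcroft_gault(70, 80, "male", 1.0)    # 77.78
#' cockcroft_gault(70, 80, "female", 1.0)  # 66.11
cockcroft_gault <- function(age_y, weight_kg, sex, creatinine_mg_dl) {
  if (any(creatinine_mg_dl <= 0)) stop("creatinine must be positive")
  if (any(age_y >= 140)) stop("age must be below 140 years")
  if (any(weight_kg <= 0)) stop("weight must be positive")
  sex <- as.character(sex)
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
  crcl <- (140 - age_y) * weight_kg / (72 * creatinine_mg_dl)
  ifelse(sex == "female", 0.85 * crcl, crcl)
}

#' Bland-Altman method agreement
#'
#' Compares two paired measurement series: mean difference (bias), 95%
#' limits of agreement (bias +/- 1.96 SD of the differences), squared
#' Pearson correlation, and the largest absolute difference expressed in
#' pooled-measurement standard deviations.
#'
#' @param x,y Paired numeric vectors (n >= 3).
#' @param transform `"raw"`, `"standardize"` (z-score each series) or
#'   `"log"` (natural log, requires positive values) applied before
#'   differencing.
#' @return List of class `agreement_result`: `bias`, `loa_low`, `loa_high`,
#'   `sd_diff`, `r2`, `max_abs_diff_sd`, `n`.
#' @export
bland_altman <- function(x, y, transform = c("raw", "standardize", "log")) {
  transform <- match.arg(transform)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (transform == "standardize") {
    x <- as.vector(scale(x)); y <- as.vector(scale(y))
  } else if (transform == "log") {
    if (any(x <= 0) || any(y <= 0)) stop("log transform requires positives")
    x <- log(x); y <- log(y)
  }
  d <- x - y
  bias <- mean(d)
  sdd <- sd(d)
  pooled_sd <- sd(c(x, y))
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * sdd,
                 loa_high = bias + 1.96 * sdd,
                 sd_diff = sdd,
                 r2 = cor(x, y)^2,
                 max_abs_diff_sd = max(abs(d)) /
                   ifelse(pooled_sd > 0, pooled_sd, NA_real_),
                 n = n), class = "agreement_result")
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up adjustment with monotonicity enforced; equivalent to the
#' classical linear step-up procedure.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values in the original order.
#' @export
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_fdr <- function(pvalues) {
  if (any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(pvalues)
  if (m == 0) return(numeric(0))
  ord <- order(pvalues)
  q <- pvalues[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Univariate case-control screen of the marker panel
#'
#' Per-marker two-sided Welch t test on log2 abundances, Benjamini-Hochberg
#' q-values across markers, and the linear-scale ratio of group means
#' (HF / control).
#'
#' @param markers Matrix/data.frame of positive abundances (subjects x
#'   markers).
#' @param groups Vector with two levels; `"HF"` (or the second level) is
#'   the numerator group.
#' @param alpha Significance threshold on q.
#' @return Data frame of class `screen_result`: `marker`, `ratio`,
#'   `t_stat`, `p`, `q`, `significant`, `direction`.
#' @export
univariate_screen <- function(markers, groups, alpha = 0.05) {
  markers <- as.matrix(markers)
  g <- as.character(groups)
  lev <- unique(g)
  if (length(lev) != 2) stop("exactly two groups are required")
  hf_lev <- if ("HF" %in% lev) "HF" else lev[1]
  ct_lev <- setdiff(lev, hf_lev)
  if (sum(g == hf_lev) < 2 || sum(g == ct_lev) < 2)
    stop("each group needs at least 2 subjects")
  if (any(markers <= 0)) stop("marker abundances must be positive")
  lx <- log2(markers)
  res <- vapply(seq_len(ncol(markers)), function(j) {
    tt <- t.test(lx[g == hf_lev, j], lx[g == ct_lev, j])
    c(ratio = mean(markers[g == hf_lev, j]) /
        mean(markers[g == ct_lev, j]),
      t_stat = unname(tt$statistic), p = tt$p.value)
  }, numeric(3))
  out <- data.frame(marker = colnames(markers),
                    ratio = res["ratio", ], t_stat = res["t_stat", ],
                    p = res["p", ], q = bh_fdr(res["p", ]),
                    stringsAsFactors = FALSE)
  out$significant <- out$q < alpha
  out$direction <- ifelse(out$ratio > 1, "up", "down")
  class(out) <- c("screen_result", "data.frame")
  out
}

#' Correlation structure and cluster analysis of the panel
#'
#' Pearson correlation matrix, average-linkage hierarchical clustering on
#' the distance `1 - r`, cluster labels at `k` groups and the dendrogram
#' leaf ordering (the heatmap ordering).
#'
#' @param x Matrix (subjects x variables), >= 3 variables and subjects.
#' @param k Number of clusters to cut (default 3).
#' @return List of class `correlation_structure`: `cor` (matrix),
#'   `clusters` (named integer), `order` (leaf ordering), `mean_r`,
#'   `mean_abs_r`, `hclust`.
#' @export
correlation_structure <- function(x, k = 3) {
  x <- as.matrix(x)
  if (ncol(x) < 3 || nrow(x) < 3) stop("need >= 3 variables and subjects")
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant column(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  r <- cor(x)
  hc <- hclust(as.dist(1 - r), method = "average")
  cl <- cutree(hc, k = k)
  off <- r[upper.tri(r)]
  structure(list(cor = r, clusters = cl, order = hc$order,
                 mean_r = mean(off), mean_abs_r = mean(abs(off)),
                 hclust = hc), class = "correlation_structure")
}

#' Cohort description table
#'
#' Medians with quartiles (type-7, linear interpolation) per group for
#' continuous variables, counts with percentages for categorical ones, and
#' a per-variable group-comparison p-value (Welch t for continuous,
#' chi-squared -- or Fisher's exact when any expected cell is below 5 --
#' for categorical).
#'
#' @param table Cohort data frame.
#' @param group_col Name of the grouping column.
#' @param vars Variables to describe (default: all except the group).
#' @return Data frame with one row per variable.
#' @export
describe_cohort <- function(table, group_col = "group", vars = NULL) {
  if (!group_col %in% names(table)) stop("missing group column")
  g <- as.character(table[[group_col]])
  lev <- unique(g)
  if (is.null(vars)) vars <- setdiff(names(table), group_col)
  fmt_cont <- function(v) {
    qs <- quantile(v, c(0.5, 0.25, 0.75), na.rm = TRUE, type = 7)
    sprintf("%.3g (%.3g; %.3g)", qs[1], qs[2], qs[3])
  }
  rows <- lapply(vars, function(nm) {
    v <- table[[nm]]
    if (is.numeric(v)) {
      p <- if (length(lev) == 2)
        tryCatch(t.test(v[g == lev[1]], v[g == lev[2]])$p.value,
                 error = function(e) NA_real_) else NA_real_
      cells <- vapply(lev, function(l) fmt_cont(v[g == l]), character(1))
      data.frame(variable = nm, type = "continuous",
                 as.list(setNames(cells, lev)), p = p,
                 check.names = FALSE, stringsAsFactors = FALSE)
    } else {
      v <- as.character(v)
      top <- names(sort(base::table(v), decreasing = TRUE))[1]
      cells <- vapply(lev, function(l) {
        n1 <- sum(v == top & g == l)
        sprintf("%d (%.0f%%)", n1, 100 * n1 / sum(g == l))
      }, character(1))
      tabxg <- base::table(v, g)
      p <- tryCatch({
        if (any(suppressWarnings(chisq.test(tabxg)$expected) < 5))
          fisher.test(tabxg)$p.value
        else chisq.test(tabxg)$p.value
      }, error = function(e) NA_real_)
      data.frame(variable = paste0(nm, " = ", top), type = "categorical",
                 as.list(setNames(cells, lev)), p = p,
                 check.names = FALSE, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index
#'
#' Agreement between two partitions, corrected for chance; 1 for identical
#' partitions, approximately 0 for independent ones.
#'
#' @param a,b Cluster label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("partitions must have equal length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxind <- (sum_a + sum_b) / 2
  if (maxind == expected) return(1)
  (sum_ij - expected) / (maxind - expected)
}
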