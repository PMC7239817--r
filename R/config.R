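#' Cohort simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()] and its
#' component generators. The defaults constitute the package's calibrated
#' "reference world": a 66-patient / 28-control cohort with a 92-marker
#' panel organised in three correlated clusters, a 15-variable physiology
#' block driven by a shared latent severity, group abundance ratios planted
#' for 39 markers, and Weibull proportional-hazards survival calibrated to
#' 42/66 expected deaths with a median decedent time of 1.8 years.
#'
#' @param n_hf,n_ctrl Number of heart-failure and control subjects.
#' @param cluster_sizes Integer vector of three marker-cluster sizes; must
#'   sum to the number of panel markers.
#' @param within_corr,between_corr Log-scale marker correlation within and
#'   between clusters. Defaults are calibrated by
#'   [calibrate_block_correlations()] so that the population mean pairwise
#'   correlation is 0.25 and the first three principal components carry 48%
#'   of the variance. Must satisfy `0 <= between_corr < within_corr < 1`.
#' @param marker_panel Data frame as returned by [default_marker_panel()];
#'   its `ratio` column is the per-marker HF/control linear-scale mean ratio
#'   (the effect profile) and `severity_loading` the per-marker loading on
#'   latent severity.
#' @param physiology_spec Data frame as returned by
#'   [default_physiology_spec()].
#' @param severity_coupling Named numeric: correlation of each category's
#'   latent factor with severity (names `physical_capacity`,
#'   `daily_activity`, `myocardial_function`). Scaling these is the
#'   `severity_link` dial: 0 decouples physiology from severity entirely.
#' @param marker_category_loading Optional data frame (`column`,
#'   `category`, `loading`) planting *direct* dependencies between a
#'   marker's log abundance and a category's latent factor (the star
#'   structures ARACNE-style inference is designed to recover). `NULL`
#'   (default) plants none; marker-category covariance then flows only
#'   through severity.
#' @param baseline_hazard Weibull rate parameter (events/year scale).
#' @param hazard_shape Weibull shape; 1 gives exponential event times.
#' @param severity_log_hazard Log-hazard increment per severity SD (gamma).
#' @param ctrl_hazard_mult Hazard multiplier applied to controls.
#' @param censor_time Administrative censoring horizon (years).
#' @param entry_spread Staggered-entry width (years): each subject's
#'   censoring time is `censor_time - U(0, entry_spread)`.
#' @param wear_min_day Named numeric (`hf`, `ctrl`): accelerometer wear
#'   minutes per day.
#' @param accel_days Days of accelerometer recording.
#' @param seed Integer seed; fixed seed implies a bit-identical cohort.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(seed = 1)
#' cfg$n_hf
cohort_config <- function(n_hf = 66L,
                          n_ctrl = 28L,
                          cluster_sizes = c(31L, 31L, 30L),
                          within_corr = NULL,
                          between_corr = NULL,
                          marker_panel = default_marker_panel(),
                          physiology_spec = default_physiology_spec(),
                          severity_coupling = c(physical_capacity = 0.30,
                                                daily_activity = 0.30,
                                                myocardial_function = 0.18),
                          marker_category_loading = NULL,
                          baseline_hazard = 0.3168,
                          hazard_shape = 2.44,
                          severity_log_hazard = 1.4,
                          ctrl_hazard_mult = 0.15,
                          censor_time = 5,
                          entry_spread = 3,
                          wear_min_day = c(hf = 645, ctrl = 822),
                          accel_days = 7L,
                          seed = 1L) {
  p <- nrow(marker_panel)
  if (is.null(within_corr) || is.null(between_corr)) {
    wb <- calibrate_block_correlations(p, cluster_sizes,
                                       target_mean_r = 0.25,
                                       target_top3_var = 0.48)
    within_corr <- wb$within
    between_corr <- wb$between
  }
  cfg <- structure(list(
    n_hf = as.integer(n_hf), n_ctrl = as.integer(n_ctrl),
    p_markers = p,
    cluster_sizes = as.integer(cluster_sizes),
    within_corr = within_corr, between_corr = between_corr,
    marker_panel = marker_panel,
    physiology_spec = physiology_spec,
    severity_coupling = severity_coupling,
    marker_category_loading = marker_category_loading,
    baseline_hazard = baseline_hazard,
    hazard_shape = hazard_shape,
    severity_log_hazard = severity_log_hazard,
    ctrl_hazard_mult = ctrl_hazard_mult,
    censor_time = censor_time,
    entry_spread = entry_spread,
    wear_min_day = wear_min_day,
    accel_days = as.integer(accel_days),
    seed = as.integer(seed)), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_hf >= 0, cfg$n_ctrl >= 0)
  if (length(cfg$cluster_sizes) != 3L)
    stop("cluster_sizes must have length 3")
  if (sum(cfg$cluster_sizes) != cfg$p_markers)
    stop("cluster_sizes must sum to the number of panel markers (",
         cfg$p_markers, ")")
  if (!(cfg$between_corr >= 0 && cfg$between_corr < cfg$within_corr &&
        cfg$within_corr < 1))
    stop("need 0 <= between_corr < within_corr < 1, got (",
         cfg$within_corr, ", ", cfg$between_corr, ")")
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive")
  if (cfg$hazard_shape <= 0) stop("hazard_shape must be positive")
  if (cfg$censor_time <= 0) stop("censor_time must be positive")
  if (cfg$entry_spread < 0 || cfg$entry_spread >= cfg$censor_time)
    stop("entry_spread must lie in [0, censor_time)")
  if (any(cfg$marker_panel$ratio <= 0))
    stop("marker effect ratios must be positive")
  needed <- c("physical_capacity", "daily_activity", "myocardial_function")
  if (!all(needed %in% names(cfg$severity_coupling)))
    stop("severity_coupling must name all three categories")
  if (any(abs(cfg$severity_coupling) >= 1))
    stop("severity_coupling entries must lie in (-1, 1)")
  bad <- setdiff(unique(cfg$physiology_spec$category), needed)
  if (length(bad))
    stop("unknown physiology category: ", paste(bad, collapse = ", "))
  mcl <- cfg$marker_category_loading
  if (!is.null(mcl)) {
    if (!all(c("column", "category", "loading") %in% names(mcl)))
      stop("marker_category_loading needs columns column/category/loading")
    if (!all(mcl$column %in% cfg$marker_panel$column))
      stop("marker_category_loading names unknown marker(s): ",
           paste(setdiff(mcl$column, cfg$marker_panel$column),
                 collapse = ", "))
    if (!all(mcl$category %in% needed))
      stop("marker_category_loading names unknown category(s)")
  }
  invisible(cfg)
}

#' Calibrate within/between cluster correlations
#'
#' Finds the within-cluster correlation `w` and between-cluster correlation
#' `b` of a three-block equicorrelation model such that (i) the mean
#' off-diagonal entry of the population correlation matrix equals
#' `target_mean_r` and (ii) the share of variance carried by the three
#' leading eigenvalues is within 0.03 of `target_top3_var`.
#'
#' For a block-equicorrelation matrix the `p - 3` non-leading eigenvalues
#' all equal `1 - w`, so the leading-three share is `(3 + (p - 3) w) / p`
#' regardless of `b`; `w` is found by bisection on that relation and `b`
#' then solves the linear mean-correlation constraint. Infeasible targets
#' (e.g. a top-three share smaller than what independence already gives, or
#' a mean correlation requiring `b >= w` or `b < 0`) raise an error rather
#' than being clipped.
#'
#' @param p_markers Number of variables.
#' @param cluster_sizes Three block sizes summing to `p_markers`.
#' @param target_mean_r Desired population mean off-diagonal correlation.
#' @param target_top3_var Desired leading-three eigenvalue share (fraction).
#' @return List with elements `within`, `between`, `mean_r`, `top3_var`.
#' @export
#' @examples
#' calibrate_block_correlations(92, c(31, 31, 30), 0.25, 0.48)
calibrate_block_correlations <- function(p_markers, cluster_sizes,
                                         target_mean_r, target_top3_var) {
  p <- p_markers
  k <- cluster_sizes
  if (length(k) != 3L || sum(k) != p)
    stop("cluster_sizes must be three counts summing to p_markers")
  if (!(target_mean_r > 0 && target_mean_r < 1))
    stop("target_mean_r must lie in (0, 1)")
  top3_share <- function(w) (3 + (p - 3) * w) / p
  f <- function(w) top3_share(w) - target_top3_var
  if (f(0) > 1e-12 || f(1) < -1e-12)
    stop("infeasible targets: top-3 variance share ", target_top3_var,
         " is outside the attainable range [", round(top3_share(0), 4),
         ", 1] for p = ", p)
  w <- uniroot(f, c(0, 1), tol = 1e-12)$root
  n_within <- sum(k * (k - 1))
  n_between <- p * (p - 1) - n_within
  if (n_between == 0) {
    b <- w
  } else {
    b <- (target_mean_r * p * (p - 1) - n_within * w) / n_between
  }
  ## degenerate single-component case: equicorrelation w = b = r
  if (abs(b - w) < 1e-10) b <- w
  if (b < -1e-12 || b > w + 1e-12)
    stop("infeasible targets: solving mean r = ", target_mean_r,
         " at w = ", round(w, 4), " requires b = ", round(b, 4),
         " outside [0, w]")
  b <- min(max(b, 0), w)
  ## confirm on the reduced 3 x 3 eigenproblem that the three block
  ## eigenvalues are the leading ones and the matrix is positive definite
  C <- diag(1 + (k - 1) * w)
  for (i in 1:3) for (j in 1:3) if (i != j) C[i, j] <- b * sqrt(k[i] * k[j])
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0 || (b < w && min(ev) < 1 - w - 1e-9))
    stop("calibrated (w, b) = (", round(w, 4), ", ", round(b, 4),
         ") does not yield the intended spectral structure")
  achieved <- sum(ev) / p
  if (abs(achieved - target_top3_var) > 0.03)
    stop("calibration failed to reach top-3 target within 0.03")
  list(within = w, between = b,
       mean_r = (n_within * w + n_between * b) / (p * (p - 1)),
       top3_var = achieved)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config:", x$n_hf, "HF /", x$n_ctrl, "controls,",
      x$p_markers, "markers in clusters (",
      paste(x$cluster_sizes, collapse = ", "), ")\n")
  cat(sprintf("  marker correlations: within %.3f, between %.3f\n",
              x$within_corr, x$between_corr))
  cat(sprintf("  survival: lambda %.4f/y, shape %.2f, gamma %.2f, censor U(%g, %g)\n",
              x$baseline_hazard, x$hazard_shape, x$severity_log_hazard,
              x$censor_time - x$entry_spread, x$censor_time))
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
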