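## Synthetic cohort generators. All generators are pure functions of the
## supplied configuration and of R's RNG state; simulate_cohort() seeds the
## RNG once from config$seed so a fixed seed reproduces the cohort exactly.

#' Simulate marker abundances
#'
#' Draws log-scale marker values from the three-block equicorrelation model
#' (constructed exactly via its factor representation: a global factor with
#' weight `sqrt(b)`, a cluster factor with weight `sqrt(w - b)` and
#' idiosyncratic noise with weight `sqrt(1 - w)`), adds the per-marker
#' severity loading times the subject's latent severity and the log effect
#' ratio for heart-failure subjects, and exponentiates to strictly positive
#' abundances. Because the group shift acts on the log scale with equal
#' variances in both groups, the expected linear-scale HF/control mean ratio
#' equals the panel `ratio` exactly.
#'
#' When `config$marker_category_loading` plants direct marker-category
#' dependencies, the named markers additionally load on the corresponding
#' category latent factors (shared with [simulate_physiology()] when both
#' are orchestrated by [simulate_cohort()]).
#'
#' @param config A [cohort_config()].
#' @param severities Numeric vector of latent severities, one per subject.
#' @param groups Character/factor vector (`"HF"`/`"control"`) per subject.
#' @param category_factors Optional matrix (subjects x 3, columns named by
#'   category) of latent category factors; drawn internally when `NULL`.
#' @return Numeric matrix (subjects x markers) of positive abundances, with
#'   marker columns named per the panel.
#' @export
simulate_markers <- function(config, severities, groups,
                             category_factors = NULL) {
  n <- length(severities)
  if (length(groups) != n)
    stop("severities and groups must have equal length")
  w <- config$within_corr; b <- config$between_corr
  if (b < 0 || b >= w || w >= 1)
    stop("correlation parameters (w, b) = (", w, ", ", b,
         ") do not define a positive-definite block model")
  panel <- config$marker_panel
  p <- nrow(panel)
  blk <- panel$cluster
  g  <- rnorm(n)                              # global factor
  f  <- matrix(rnorm(n * 3L), n, 3L)          # cluster factors
  e  <- matrix(rnorm(n * p), n, p)            # idiosyncratic
  z  <- sqrt(b) * g + sqrt(w - b) * f[, blk, drop = FALSE] +
    sqrt(1 - w) * e
  z  <- z + outer(severities, panel$severity_loading)
  mcl <- config$marker_category_loading
  if (!is.null(mcl) && nrow(mcl)) {
    cats <- c("physical_capacity", "daily_activity", "myocardial_function")
    if (is.null(category_factors)) {
      category_factors <- matrix(rnorm(n * 3L), n, 3L,
                                 dimnames = list(NULL, cats))
    }
    for (i in seq_len(nrow(mcl))) {
      j <- match(mcl$column[i], panel$column)
      z[, j] <- z[, j] +
        mcl$loading[i] * category_factors[, mcl$category[i]]
    }
  }
  is_hf <- as.integer(groups == "HF")
  z  <- z + outer(is_hf, log(panel$ratio))
  x  <- exp(z)
  colnames(x) <- panel$column
  x
}

#' Simulate the physiology block
#'
#' Each variable is generated as
#' `location[group] + sd[group] * (a * severity + b * eta_category + u * noise)`
#' where `a = -coupling[category] * loading * orientation` (so that a higher
#' severity always degrades function), `eta_category` is a shared
#' category-level factor and `u` completes the unit variance. Group
#' locations and spreads default to the observed cohort medians and
#' IQR-derived standard deviations. `pct_inactive` is returned as exactly
#' `100 - pct_active`.
#'
#' @inheritParams simulate_markers
#' @return Numeric matrix (subjects x variables).
#' @export
simulate_physiology <- function(config, severities, groups,
                                category_factors = NULL) {
  n <- length(severities)
  spec <- config$physiology_spec
  coup <- config$severity_coupling
  bad <- setdiff(spec$category, names(coup))
  if (length(bad))
    stop("no severity coupling defined for category: ",
         paste(bad, collapse = ", "))
  cats <- unique(spec$category)
  eta <- if (is.null(category_factors)) {
    matrix(rnorm(n * length(cats)), n, length(cats),
           dimnames = list(NULL, cats))
  } else category_factors
  is_hf <- groups == "HF"
  out <- matrix(NA_real_, n, nrow(spec),
                dimnames = list(NULL, spec$variable))
  for (v in seq_len(nrow(spec))) {
    cc <- coup[[spec$category[v]]]
    l  <- spec$loading[v] * spec$orientation[v]
    a  <- -cc * l
    bb <- sqrt(1 - cc^2) * l
    u  <- sqrt(max(0, 1 - a^2 - bb^2))
    zstd <- a * severities + bb * eta[, spec$category[v]] + u * rnorm(n)
    loc <- ifelse(is_hf, spec$loc_hf[v], spec$loc_ctrl[v])
    sdv <- ifelse(is_hf, spec$sd_hf[v], spec$sd_ctrl[v])
    out[, v] <- loc + sdv * zstd
  }
  ## physical floors and complements
  out[, "vo2peak"] <- pmax(out[, "vo2peak"], 1)
  for (v in c("psv", "septal_e", "lateral_e", "e_over_e", "pa_pressure",
              "la_area", "lvedd", "tapse", "lvef"))
    out[, v] <- pmax(out[, v], 0.001)
  out[, "pct_active"] <- pmin(pmax(out[, "pct_active"], 1), 99)
  out[, "pct_inactive"] <- 100 - out[, "pct_active"]
  out
}

#' Simulate survival times
#'
#' Event times follow a Weibull proportional-hazards model:
#' `S(t | severity) = exp(-(lambda t)^shape * exp(gamma * severity + log(mult)))`
#' with `mult = 1` for heart-failure subjects and `ctrl_hazard_mult` for
#' controls. `shape = 1` recovers exponential event times with rate
#' `lambda * exp(gamma * severity)`. Censoring combines administrative
#' cut-off at `censor_time` with uniform staggered entry over
#' `entry_spread` years, i.e. each subject's censoring time is
#' `censor_time - U(0, entry_spread)`.
#'
#' @inheritParams simulate_markers
#' @return Data frame with columns `time` (> 0) and `event` (0/1).
#' @export
simulate_survival <- function(config, severities, groups) {
  n <- length(severities)
  lam <- config$baseline_hazard
  kap <- config$hazard_shape
  gam <- config$severity_log_hazard
  mult <- ifelse(groups == "HF", 1, config$ctrl_hazard_mult)
  ## inverse-transform draw: (lambda T)^shape ~ Exp(rate = exp(gamma s) mult)
  tt <- (rexp(n) / (exp(gam * severities) * mult))^(1 / kap) / lam
  cens <- config$censor_time - runif(n, 0, config$entry_spread)
  event <- as.integer(tt <= cens)
  data.frame(time = pmin(tt, cens), event = event)
}

#' Simulate a full case-control cohort
#'
#' Orchestrates the marker, physiology, survival and (optionally)
#' accelerometer-trace generators on a shared vector of latent severities,
#' and returns the joined subject table together with the planted ground
#' truth used by recovery tests.
#'
#' @param config A [cohort_config()].
#' @param include_traces Logical; also generate per-subject accelerometer
#'   epoch traces (list of data frames), which is slower.
#' @return An object of class `hf_cohort`: a list with elements
#'   \describe{
#'     \item{table}{data.frame, one row per subject: `id`, `group`,
#'       demographics, `marker_001`..., physiology columns, `time`, `event`.}
#'     \item{traces}{named list of epoch traces, or `NULL`.}
#'     \item{truth}{`ground_truth` list: severities, the marker panel with
#'       planted ratios and severity loadings, planted marker-category
#'       edges, and per-marker induced log hazard per severity SD.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' dim(coh$table)
simulate_cohort <- function(config = cohort_config(),
                            include_traces = FALSE) {
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_hf + config$n_ctrl
  groups <- rep(c("HF", "control"), c(config$n_hf, config$n_ctrl))
  severities <- rnorm(n)
  ## demographics (medians/IQRs follow the cohort description)
  age <- round(ifelse(groups == "HF", rnorm(n, 70, 8.2),
                      rnorm(n, 70.5, 5.3)))
  age <- pmin(pmax(age, 35), 95)
  sex <- ifelse(runif(n) < ifelse(groups == "HF", 0.20, 0.71),
                "female", "male")
  weight <- round(ifelse(groups == "HF", rnorm(n, 84, 15),
                         rnorm(n, 72, 13)), 1)
  weight <- pmax(weight, 40)
  creatinine <- round(exp(ifelse(groups == "HF",
                                 rnorm(n, log(1.3), 0.25),
                                 rnorm(n, log(0.95), 0.2))), 2)
  cats <- c("physical_capacity", "daily_activity", "myocardial_function")
  eta <- matrix(rnorm(n * 3L), n, 3L, dimnames = list(NULL, cats))
  markers <- simulate_markers(config, severities, groups,
                              category_factors = eta)
  phys <- simulate_physiology(config, severities, groups,
                              category_factors = eta)
  surv <- simulate_survival(config, severities, groups)
  tab <- data.frame(
    id = sprintf("S%03d", seq_len(n)),
    group = groups, age = age, sex = sex, weight = weight,
    creatinine = creatinine, severity = severities,
    stringsAsFactors = FALSE)
  tab <- cbind(tab, as.data.frame(markers), as.data.frame(phys), surv)
  traces <- NULL
  if (include_traces) {
    traces <- lapply(seq_len(n), function(i)
      simulate_accel_trace(config, tab[i, , drop = FALSE]))
    names(traces) <- tab$id
  }
  panel <- config$marker_panel
  loaded <- panel$column[panel$severity_loading != 0]
  planted_edges <- if (length(loaded)) {
    expand.grid(marker = loaded,
                category = names(config$severity_coupling),
                stringsAsFactors = FALSE)
  } else {
    data.frame(marker = character(), category = character())
  }
  if (!is.null(config$marker_category_loading)) {
    direct <- config$marker_category_loading
    planted_edges <- unique(rbind(
      planted_edges,
      data.frame(marker = direct$column, category = direct$category,
                 stringsAsFactors = FALSE)))
  }
  truth <- structure(list(
    severities = severities,
    panel = panel,
    planted_edges = planted_edges,
    marker_log_hazard = setNames(
      config$severity_log_hazard * panel$severity_loading /
        sqrt(1 + panel$severity_loading^2),
      panel$column)), class = "ground_truth")
  structure(list(table = tab, traces = traces, truth = truth,
                 config = config), class = "hf_cohort")
}

#' @export
print.hf_cohort <- function(x, ...) {
  cat("hf_cohort:", sum(x$table$group == "HF"), "HF /",
      sum(x$table$group == "control"), "controls,",
      x$config$p_markers, "markers;",
      sum(x$table$event), "events\n")
  invisible(x)
}

#' Marker column names of a cohort
#' @param x An `hf_cohort` or `cohort_config`.
#' @return Character vector of marker column names.
#' @export
marker_columns <- function(x) {
  cfg <- if (inherits(x, "hf_cohort")) x$config else x
  cfg$marker_panel$column
}

#' Write / read a cohort table
#'
#' The subject table is serialised as tab-separated text (one row per
#' subject); ground truth, when present, as JSON next to it; accelerometer
#' traces as one CSV per subject (`<id>_trace.csv` with columns
#' `timestamp`, `cpm`) in a `traces/` subdirectory.
#'
#' @param cohort An `hf_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab_path <- file.path(dir, "cohort.tsv")
  write.table(cohort$table, tab_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- tab_path
  if (!is.null(cohort$truth)) {
    gt_path <- file.path(dir, "ground_truth.json")
    jsonlite::write_json(unclass(cohort$truth), gt_path, digits = NA,
                         auto_unbox = TRUE, dataframe = "columns")
    paths <- c(paths, gt_path)
  }
  if (!is.null(cohort$traces)) {
    tdir <- file.path(dir, "traces")
    dir.create(tdir, showWarnings = FALSE)
    for (id in names(cohort$traces)) {
      tp <- file.path(tdir, paste0(id, "_trace.csv"))
      write.csv(cohort$traces[[id]][, c("timestamp", "cpm")], tp,
                row.names = FALSE, quote = FALSE)
      paths <- c(paths, tp)
    }
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @param check Logical; run [validate_inputs()] on the table first.
#' @export
read_cohort <- function(dir, check = TRUE) {
  tab_path <- file.path(dir, "cohort.tsv")
  if (check) {
    rep <- validate_inputs(tab_path)
    if (!rep$ok)
      stop("cohort table failed validation: ",
           paste(rep$findings$message, collapse = "; "))
  }
  tab <- read.delim(tab_path, stringsAsFactors = FALSE)
  tdir <- file.path(dir, "traces")
  traces <- NULL
  if (dir.exists(tdir)) {
    files <- list.files(tdir, pattern = "_trace\\.csv$", full.names = TRUE)
    traces <- lapply(files, read.csv)
    names(traces) <- sub("_trace\\.csv$", "", basename(files))
  }
  structure(list(table = tab, traces = traces, truth = NULL, config = NULL),
            class = "hf_cohort")
}
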