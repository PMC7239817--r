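## End-to-end pipeline: simulate (or load) a cohort, accelerometry QC,
## univariate screen, OPLS-DA, category PCA, MI network, survival, report.
## Every stage writes plain-text outputs and is listed in a manifest with
## input hashes and the seed it ran under.

#' Pipeline run configuration
#'
#' @param out_dir Output directory.
#' @param seed Master seed; per-stage seeds are derived from it by stable
#'   hashing of the stage name.
#' @param cohort A `cohort_config` for simulation, or `NULL` with
#'   `cohort_dir` pointing at an existing cohort.
#' @param cohort_dir Directory holding `cohort.tsv` (+ optional `traces/`)
#'   when not simulating.
#' @param stages Stages to run, in dependency order.
#' @param fdr,r_threshold,vip_threshold,active_cpm,min_wear_days,
#'   dpi_tolerance,b_perm,b_boot Analysis thresholds (surfaced, nothing
#'   hard-coded downstream).
#' @param include_traces Simulate accelerometer traces (slower).
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir,
                       seed = 1L,
                       cohort = cohort_config(seed = seed),
                       cohort_dir = NULL,
                       stages = c("simulate", "accel_qc", "screen", "opls",
                                  "pca", "network", "survival", "report"),
                       fdr = 0.05, r_threshold = 0.2, vip_threshold = 0.8,
                       active_cpm = 100, min_wear_days = 3,
                       dpi_tolerance = 0.15,
                       b_perm = 1000L, b_boot = 1000L,
                       include_traces = FALSE) {
  stopifnot(fdr > 0, fdr < 1, r_threshold >= 0, r_threshold < 1,
            vip_threshold >= 0, active_cpm >= 0, min_wear_days >= 0,
            dpi_tolerance >= 0, dpi_tolerance < 1,
            b_perm >= 100, b_boot >= 100)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 cohort = cohort, cohort_dir = cohort_dir,
                 stages = stages, fdr = fdr, r_threshold = r_threshold,
                 vip_threshold = vip_threshold, active_cpm = active_cpm,
                 min_wear_days = min_wear_days,
                 dpi_tolerance = dpi_tolerance,
                 b_perm = as.integer(b_perm), b_boot = as.integer(b_boot),
                 include_traces = include_traces),
            class = "run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Recognised top-level keys mirror the arguments of [run_config()];
#' a `cohort:` block may override [cohort_config()] scalars (`n_hf`,
#' `n_ctrl`, `seed`, `baseline_hazard`, ...).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  coh_args <- y$cohort %||% list()
  y$cohort <- NULL
  args <- y
  args$cohort <- do.call(cohort_config, coh_args)
  if (is.null(args$out_dir)) stop("config must set out_dir")
  do.call(run_config, args)
}

stage_seed <- function(master, stage) {
  (as.integer(master) + sum(utf8ToInt(stage)) * 7919L) %% .Machine$integer.max
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order. A stage failure
#' halts the run with the failing stage named; outputs already written are
#' retained. The manifest (`manifest.json`) lists every output file with
#' its MD5 hash, the per-stage seeds and the stage funnel counts, so a
#' rerun with the same configuration and seed is byte-identical.
#'
#' @param config A [run_config()].
#' @return List of class `run_report`: `manifest`, `funnel`, stage
#'   outputs.
#' @export
run_pipeline <- function(config) {
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  seeds <- list()
  funnel <- list()
  results <- list()
  log_msg <- function(...) message("[hfnet] ", ...)
  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    seeds[[name]] <<- stage_seed(config$seed, name)
    log_msg("stage ", name, " (seed ", seeds[[name]], ")")
    tryCatch(fun(seeds[[name]]),
             error = function(e)
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE))
  }

  ## -- simulate or load ------------------------------------------------
  cohort <- NULL
  run_stage("simulate", function(sd) {
    if (is.null(config$cohort)) {
      log_msg("no simulation config; loading cohort from cohort_dir")
      return(NULL)
    }
    cfg <- config$cohort
    cfg$seed <- sd
    cohort <<- simulate_cohort(cfg, include_traces = config$include_traces)
    files <<- c(files, write_cohort(cohort, out))
  })
  if (is.null(cohort)) {
    if (is.null(config$cohort_dir))
      stop("no cohort: enable the simulate stage or set cohort_dir")
    cohort <- read_cohort(config$cohort_dir)
  }
  tab <- cohort$table
  mcols <- grep("^marker_", names(tab), value = TRUE)

  ## -- accelerometry QC -------------------------------------------------
  run_stage("accel_qc", function(sd) {
    if (is.null(cohort$traces)) {
      log_msg("no traces present; activity columns taken as measured")
      return(NULL)
    }
    summ <- do.call(rbind, lapply(names(cohort$traces), function(id) {
      tr <- cohort$traces[[id]]
      s <- summarize_activity(tr, detect_nonwear(tr),
                              active_threshold = config$active_cpm,
                              min_wear_days = config$min_wear_days)
      cbind(id = id, s)
    }))
    path <- file.path(out, "activity_summary.tsv")
    write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    keep <- summ$id[summ$valid]
    dropped <- setdiff(tab$id, keep)
    if (length(dropped))
      log_msg("excluding ", length(dropped),
              " subject(s) with < ", config$min_wear_days, " wear days")
    idx <- match(tab$id, summ$id)
    for (v in c("pct_active", "pct_inactive", "skewness"))
      tab[[v]] <- summ[[v]][idx]
    tab <<- tab[tab$id %in% keep, , drop = FALSE]
    results$activity <<- summ
  })

  ## -- univariate screen -------------------------------------------------
  screen <- NULL
  run_stage("screen", function(sd) {
    screen <<- univariate_screen(tab[, mcols], tab$group,
                                 alpha = config$fdr)
    path <- file.path(out, "screen.tsv")
    write.table(screen, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    funnel$discriminating <<- sum(screen$significant)
    results$screen <<- screen
  })

  ## -- OPLS-DA -----------------------------------------------------------
  run_stage("opls", function(sd) {
    if (length(unique(tab$group)) < 2) {
      log_msg("single-group cohort; OPLS-DA skipped")
      return(NULL)
    }
    X <- log2(as.matrix(tab[, mcols]))
    cv <- opls_cv(X, tab$group, folds = 7, max_orth = 3, seed = sd)
    model <- fit_opls(X, tab$group, n_orth = max(cv$n_orth, 1))
    vip <- opls_vip(model)
    boot <- opls_bootstrap(X, tab$group, B = config$b_boot,
                           n_orth = max(cv$n_orth, 1), seed = sd + 1L)
    summ <- data.frame(variable = mcols, loading = model$p_load,
                       vip = vip, lo = boot$lo, hi = boot$hi,
                       significant = boot$significant,
                       vip_flag = vip > config$vip_threshold)
    path <- file.path(out, "opls_summary.tsv")
    write.table(summ, path, sep = "\t", quote = FALSE, row.names = FALSE)
    scp <- file.path(out, "opls_scores.tsv")
    write.table(data.frame(id = tab$id, group = tab$group,
                           t_pred = model$t),
                scp, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path, scp)
    results$opls <<- list(model = model, q2 = cv$q2, n_orth = cv$n_orth,
                          table = summ)
    log_msg(sprintf("OPLS-DA: R2Y %.3f, Q2 %.3f, accuracy %.3f",
                    model$r2y, cv$q2, model$accuracy))
  })

  ## -- category PCA ------------------------------------------------------
  cs_hf <- NULL; hf_tab <- NULL
  run_stage("pca", function(sd) {
    hf_tab <<- tab[tab$group == "HF", , drop = FALSE]
    cs_hf <<- category_scores(hf_tab)
    spec <- default_physiology_spec()
    comb_vars <- spec$variable[spec$in_combined]
    comb <- fit_pca(as.matrix(hf_tab[, comb_vars]))
    path <- file.path(out, "category_scores.tsv")
    write.table(cbind(id = hf_tab$id, cs_hf$scores), path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    bp <- file.path(out, "biplot_data.tsv")
    write.table(data.frame(variable = rownames(comb$loadings),
                           comb$loadings[, 1:2]),
                bp, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path, bp)
    results$pca <<- list(category = cs_hf, combined = comb)
  })

  ## -- MI network --------------------------------------------------------
  net <- NULL
  run_stage("network", function(sd) {
    if (is.null(cs_hf)) stop("network stage requires the pca stage")
    dat <- cbind(log2(as.matrix(hf_tab[, mcols])),
                 as.matrix(cs_hf$scores))
    net <<- build_mi_network(dat, B_perm = config$b_perm,
                             B_boot = config$b_boot, seed = sd,
                             fdr = config$fdr,
                             r_threshold = config$r_threshold,
                             dpi_tolerance = config$dpi_tolerance)
    conn <- connectivity_summary(net)
    files <<- c(files, export_graph(net, file.path(out, "network")))
    cp <- file.path(out, "connectivity.tsv")
    write.table(conn$factors, cp, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <<- c(files, cp)
    funnel$connected <<- length(conn$connected_factors)
    funnel$key_factors <<- length(conn$key_factors)
    results$network <<- list(network = net, connectivity = conn)
    log_msg("network: ", sum(net$edges$retained), " retained edges, ",
            length(conn$key_factors), " key factors")
  })

  ## -- survival ----------------------------------------------------------
  run_stage("survival", function(sd) {
    if (is.null(hf_tab)) stop("survival stage requires the pca stage")
    key <- if (!is.null(results$network))
      results$network$connectivity$key_factors else character(0)
    test_set <- if (length(key)) key else {
      if (is.null(screen)) mcols else screen$marker[screen$significant]
    }
    if (length(test_set)) {
      hr <- hr_table(hf_tab, test_set, adjust = "renal_function")
      path <- file.path(out, "hr_table.tsv")
      write.table(hr, path, sep = "\t", quote = FALSE, row.names = FALSE)
      files <<- c(files, path)
      funnel$prognostic <<- sum(hr$q_crude < config$fdr, na.rm = TRUE)
      results$hr <<- hr
    }
    comb <- results$pca$combined
    orient <- default_orientation()
    sc <- comb$scores[, 1:2]
    ov <- orient[rownames(comb$loadings)]
    for (k in 1:2)
      if (sum(comb$loadings[, k] * ov) < 0) sc[, k] <- -sc[, k]
    pr <- pc_risk(sc[, 1], sc[, 2], hf_tab$time, hf_tab$event)
    km <- kaplan_meier(hf_tab$time, hf_tab$event, pr$groups)
    kp <- file.path(out, "km_quadrants.tsv")
    write.table(km, kp, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, kp)
    results$pc_risk <<- pr
  })

  ## -- report ------------------------------------------------------------
  manifest <- list(
    package_version = as.character(utils::packageVersion("hfnet")),
    master_seed = config$seed,
    stage_seeds = seeds,
    thresholds = config[c("fdr", "r_threshold", "vip_threshold",
                          "active_cpm", "min_wear_days",
                          "dpi_tolerance", "b_perm", "b_boot")],
    funnel = funnel,
    files = lapply(unique(files), function(f)
      list(path = f, md5 = unname(tools::md5sum(f)))))
  if ("report" %in% config$stages) {
    mp <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  structure(list(manifest = manifest, funnel = funnel, results = results,
                 table = tab), class = "run_report")
}

#' Validate a cohort table file
#'
#' Checks column presence and types, group labels, positive follow-up
#' times, 0/1 event flags and positive marker abundances; non-conforming
#' rows are reported with their line numbers.
#'
#' @param path Path to a `cohort.tsv`.
#' @return List of class `validation_report`: `ok`, `findings` (data frame
#'   with `row` and `message`), `n_rows`, `n_markers`.
#' @export
validate_inputs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- strsplit(readLines(path, n = 1), "\t")[[1]]
  required <- c("id", "group", "time", "event")
  miss <- setdiff(required, header)
  if (length(miss))
    stop("malformed header: missing column(s) ",
         paste(miss, collapse = ", "))
  tab <- read.delim(path, stringsAsFactors = FALSE)
  mcols <- grep("^marker_", names(tab), value = TRUE)
  findings <- list()
  add <- function(rows, msg) {
    if (length(rows))
      findings[[length(findings) + 1L]] <<-
        data.frame(row = rows, message = msg, stringsAsFactors = FALSE)
  }
  if (!length(mcols))
    add(0L, "no marker_* columns present")
  add(which(!tab$group %in% c("HF", "control")),
      "group must be 'HF' or 'control'")
  add(which(!is.finite(tab$time) | tab$time <= 0),
      "non-positive follow-up time")
  add(which(!tab$event %in% c(0, 1)), "event must be 0 or 1")
  if (length(mcols)) {
    bad_marker <- which(apply(as.matrix(tab[, mcols]) <= 0, 1, any))
    add(bad_marker, "non-positive marker abundance")
  }
  findings <- if (length(findings)) do.call(rbind, findings) else
    data.frame(row = integer(), message = character())
  structure(list(ok = nrow(findings) == 0, findings = findings,
                 n_rows = nrow(tab), n_markers = length(mcols)),
            class = "validation_report")
}
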