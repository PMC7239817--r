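## Accelerometer epoch traces: simulation and processing. Epochs are 60 s;
## counts-per-minute (cpm) are non-negative integers. Traces are data frames
## with columns `timestamp` (seconds from recording start, 60-s spacing) and
## `cpm`.

#' Simulate a 7-day accelerometer epoch trace
#'
#' Builds a day-structured counts-per-minute series: the device is worn for
#' a contiguous daytime block (waking at 07:00) and removed otherwise
#' (0 cpm). Within wear time, active (> 100 cpm) and sedentary epochs
#' alternate in bouts generated by a two-state Markov chain whose stationary
#' active fraction equals the subject's percent time active, so weekly
#' active minutes scale inversely with severity through the physiology
#' block. Sedentary epochs draw low counts (rarely zero, so detected
#' non-wear coincides with true device removal); active epochs draw a
#' right-skewed distribution above the 100-cpm threshold.
#'
#' @param config A [cohort_config()].
#' @param subject One-row data frame with at least `group`; if a
#'   `pct_active` column is present it is used as the subject's target
#'   active fraction of wear time, otherwise one is drawn from the group's
#'   default distribution.
#' @return A trace data frame with attributes `wear_truth` (logical
#'   per-epoch true wear indicator) and `target_pct_active`.
#' @export
simulate_accel_trace <- function(config, subject) {
  is_hf <- subject$group[1] == "HF"
  spec <- config$physiology_spec
  row <- spec[spec$variable == "pct_active", ]
  p_act <- if (!is.null(subject$pct_active)) {
    subject$pct_active[1] / 100
  } else {
    loc <- if (is_hf) row$loc_hf else row$loc_ctrl
    sdv <- if (is_hf) row$sd_hf else row$sd_ctrl
    min(max(rnorm(1, loc, sdv), 1), 99) / 100
  }
  wear_target <- unname(config$wear_min_day[if (is_hf) "hf" else "ctrl"])
  days <- config$accel_days
  n_epoch <- days * 1440L
  cpm <- integer(n_epoch)
  wear_truth <- logical(n_epoch)
  wake <- 7L * 60L
  ## two-state Markov chain: persistence 0.7 in the active state
  q_stay <- 0.7
  r_on <- p_act * (1 - q_stay) / (1 - p_act)
  r_on <- min(max(r_on, 0), 1)
  for (d in seq_len(days) - 1L) {
    wear_len <- round(wear_target + runif(1, -30, 30))
    wear_len <- min(max(wear_len, 60L), 1440L - wake)
    idx <- d * 1440L + wake + seq_len(wear_len)
    ## alternating activity/sedentary bouts with geometric sojourn times
    ## (the run-length representation of a two-state Markov chain)
    start_active <- runif(1) < p_act
    lens <- integer(0); states <- logical(0); cur <- start_active
    while (sum(lens) < wear_len) {
      la <- rgeom(32L, 1 - q_stay) + 1L
      ls <- rgeom(32L, max(r_on, 1e-6)) + 1L
      chunk <- if (cur) as.vector(rbind(la, ls)) else as.vector(rbind(ls, la))
      st <- rep(c(cur, !cur), 32L)
      lens <- c(lens, chunk); states <- c(states, st)
    }
    active <- rep(states, lens)[seq_len(wear_len)]
    vals <- integer(wear_len)
    n_act <- sum(active)
    if (n_act)
      vals[active] <- 101L +
        as.integer(round(rgamma(n_act, shape = 1.2, scale = 250)))
    ## sedentary wear: low counts, capped below the activity threshold and
    ## essentially never zero, so detected non-wear coincides with true
    ## device removal
    if (n_act < wear_len)
      vals[!active] <- pmin(
        as.integer(round(rgamma(wear_len - n_act, shape = 2, scale = 12))),
        99L)
    cpm[idx] <- vals
    wear_truth[idx] <- TRUE
  }
  trace <- data.frame(timestamp = (seq_len(n_epoch) - 1L) * 60,
                      cpm = cpm)
  attr(trace, "wear_truth") <- wear_truth
  attr(trace, "target_pct_active") <- p_act * 100
  trace
}

#' Integrate raw sub-minute counts into epochs
#'
#' Sums uniformly sampled raw counts into fixed-length epochs (default
#' 60 s). The sampling interval must divide the epoch length; a trailing
#' partial epoch is discarded.
#'
#' @param raw_counts Numeric vector of non-negative counts.
#' @param sample_s Sampling interval of `raw_counts` in seconds.
#' @param epoch_s Epoch length in seconds.
#' @return A trace data frame (`timestamp`, `cpm`).
#' @export
#' @examples
#' integrate_epochs(rep(2, 60), sample_s = 1)   # one epoch of 120 cpm
integrate_epochs <- function(raw_counts, sample_s, epoch_s = 60) {
  if (length(sample_s) != 1 || sample_s <= 0)
    stop("sample_s must be a single positive number")
  if (epoch_s %% sample_s != 0)
    stop("sampling interval (", sample_s,
         " s) must divide the epoch length (", epoch_s, " s)")
  if (any(raw_counts < 0)) stop("counts must be non-negative")
  per <- epoch_s %/% sample_s
  n_ep <- length(raw_counts) %/% per
  if (n_ep == 0) return(data.frame(timestamp = numeric(), cpm = numeric()))
  kept <- raw_counts[seq_len(n_ep * per)]
  cpm <- colSums(matrix(kept, nrow = per))
  data.frame(timestamp = (seq_len(n_ep) - 1) * epoch_s, cpm = cpm)
}

#' Detect accelerometer non-wear time
#'
#' Implements the Troiano-style rule: non-wear is any interval of at least
#' 60 consecutive minutes of 0 cpm, allowing up to 2 interruption minutes
#' with 1-99 cpm inside the interval (interruptions count toward its
#' length); any epoch of 100 cpm or more terminates a candidate interval,
#' and a third interruption splits it. Intervals start and end on 0-cpm
#' epochs.
#'
#' @param trace A trace data frame (`timestamp`, `cpm`) at 60-s spacing.
#' @return Logical vector, `TRUE` for wear epochs (covers every epoch).
#' @export
detect_nonwear <- function(trace) {
  cpm <- trace$cpm
  n <- length(cpm)
  if (n == 0) return(logical(0))
  ts <- trace$timestamp
  if (n > 1 && any(abs(diff(ts) - 60) > 1e-9))
    stop("trace timestamps must be at strict 60-s spacing")
  if (any(cpm < 0)) stop("cpm must be non-negative")
  wear <- rep(TRUE, n)
  pos <- 1L
  while (pos <= n) {
    if (cpm[pos] != 0) { pos <- pos + 1L; next }
    j <- pos
    interrupts <- 0L
    first_int <- NA_integer_
    last_zero <- pos
    while (j < n) {
      j <- j + 1L
      if (cpm[j] == 0) {
        last_zero <- j
      } else if (cpm[j] < 100) {
        interrupts <- interrupts + 1L
        if (is.na(first_int)) first_int <- j
        if (interrupts > 2L) break
      } else break
    }
    run_len <- last_zero - pos + 1L
    if (run_len >= 60L) {
      wear[pos:last_zero] <- FALSE
      pos <- last_zero + 1L
    } else if (!is.na(first_int)) {
      pos <- first_int + 1L
    } else {
      pos <- j + 1L
    }
  }
  wear
}

#' Summarise daily activity over wear time
#'
#' Computes wear days, the percentage of wear time spent active
#' (cpm strictly above `active_threshold`) and inactive, and the
#' adjusted Fisher-Pearson skewness of the wear-time cpm distribution.
#' Subjects with fewer than `min_wear_days` of wear are flagged invalid
#' and are excluded from downstream analysis; degenerate moment cases
#' (no wear, or zero variance) yield `NA` skewness with an explanatory
#' flag rather than silent zeros.
#'
#' @param trace A trace data frame.
#' @param mask Logical wear mask aligned to `trace` (e.g. from
#'   [detect_nonwear()]).
#' @param active_threshold Activity threshold in cpm.
#' @param min_wear_days Minimum wear days for a valid summary.
#' @return A one-row data.frame: `wear_days`, `pct_active`, `pct_inactive`,
#'   `active_min_week`, `skewness`, `valid`, `flag`.
#' @export
summarize_activity <- function(trace, mask = detect_nonwear(trace),
                               active_threshold = 100, min_wear_days = 3) {
  if (length(mask) != nrow(trace))
    stop("mask must align with the trace")
  wear_cpm <- trace$cpm[mask]
  n_wear <- length(wear_cpm)
  wear_days <- n_wear / 1440
  n_days <- max(nrow(trace) / 1440, 1e-12)
  if (n_wear == 0) {
    return(data.frame(wear_days = 0, pct_active = NA_real_,
                      pct_inactive = NA_real_, active_min_week = 0,
                      skewness = NA_real_, valid = FALSE,
                      flag = "no wear time"))
  }
  pct_active <- 100 * mean(wear_cpm > active_threshold)
  active_week <- sum(wear_cpm > active_threshold) * 7 / n_days
  m2 <- mean((wear_cpm - mean(wear_cpm))^2)
  flag <- ""
  if (m2 <= 0 || n_wear < 3) {
    skw <- NA_real_
    flag <- "degenerate cpm distribution (zero variance)"
  } else {
    g1 <- mean((wear_cpm - mean(wear_cpm))^3) / m2^1.5
    skw <- g1 * sqrt(n_wear * (n_wear - 1)) / (n_wear - 2)
  }
  valid <- wear_days >= min_wear_days
  if (!valid && flag == "") flag <- "insufficient wear time"
  data.frame(wear_days = wear_days, pct_active = pct_active,
             pct_inactive = 100 - pct_active,
             active_min_week = active_week,
             skewness = skw, valid = valid, flag = flag)
}

#' Read / write an epoch trace CSV
#' @param path File path (`timestamp`, `cpm` columns).
#' @return `read_trace`: a trace data frame.
#' @export
read_trace <- function(path) {
  tr <- read.csv(path)
  if (!all(c("timestamp", "cpm") %in% names(tr)))
    stop("trace file must have columns 'timestamp' and 'cpm': ", path)
  tr
}

#' @rdname read_trace
#' @param trace A trace data frame.
#' @export
write_trace <- function(trace, path) {
  write.csv(trace[, c("timestamp", "cpm")], path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}
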