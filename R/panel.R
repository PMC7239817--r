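## Default 92-plex marker panel and 15-variable physiology specification.
## Numeric defaults are the frozen calibration of the generator; see the
## methods vignette for how each number was chosen.

#' Default 92-marker panel specification
#'
#' Returns the per-marker specification used by [simulate_markers()]: marker
#' column name, display name, correlation cluster (three clusters of sizes
#' 31/31/30), the heart-failure vs control abundance ratio on the linear
#' scale (the planted case-control effect; 39 markers carry a ratio different
#' from 1), and the loading of the marker's log-abundance on the latent
#' disease severity (non-zero for the ten markers carrying prognostic
#' information; negative for markers that fall with worsening disease).
#'
#' @return A data.frame with columns `column` (`marker_001` ... `marker_092`),
#'   `name`, `cluster` (1-3), `ratio` (> 0) and `severity_loading`.
#' @export
#' @examples
#' panel <- default_marker_panel()
#' table(panel$cluster)
#' sum(panel$ratio != 1)
default_marker_panel <- function() {
  named <- data.frame(
    name = c("EGFR", "NT-proBNP", "PON3", "TLT-2", "TFPI", "GDF-15", "PAI",
             "U-PAR", "MMP-3", "SELP", "FABP4", "CNTN1", "TR-AP", "PDGF-A",
             "SPON1", "DLK-1", "ITGB2", "PI3", "LDL-R", "Gal-4", "ST2",
             "COL1A1", "CASP-3", "OPN", "BLM-hydrolase", "TFF3", "TfR1",
             "PLC", "CSTB", "IGFBP-7", "TNF-R1", "PECAM-1", "TNF-R2", "FAS",
             "MPO", "PSP-D", "Ep-CAM", "CCL24", "RARRES2"),
    ratio = c(0.3, 5.69, 0.1, 0.2, 0.3, 10.3, 0.1,
              3.2, 4, 0.2, 10.2, 0.5, 0.4, 0.1,
              2.6, 0.3, 0.4, 4.2, 0.3, 2.5, 3.3,
              0.4, 0.1, 2.9, 0.5, 3.1, 3.3,
              2.1, 3.2, 3.2, 2.7, 0.3, 2.4, 0.6,
              0.5, 2.8, 0.3, 0.3, 0.6),
    stringsAsFactors = FALSE)
  ## cluster themes: 1 growth/cell adhesion, 2 ECM/angiogenesis, 3 inflammation
  cl1 <- c("EGFR", "Ep-CAM", "CNTN1", "DLK-1", "LDL-R", "Gal-4", "TFF3",
           "IGFBP-7", "FABP4", "TLT-2", "TfR1", "NT-proBNP", "PON3", "TR-AP")
  cl2 <- c("MMP-3", "COL1A1", "PLC", "SPON1", "PAI", "U-PAR", "TFPI", "PI3",
           "PDGF-A", "CASP-3", "BLM-hydrolase")
  named$cluster <- ifelse(named$name %in% cl1, 1L,
                          ifelse(named$name %in% cl2, 2L, 3L))
  needed <- c(31L, 31L, 30L) - tabulate(named$cluster, 3L)
  generic <- data.frame(
    name = sprintf("M%03d", 40:92),
    ratio = 1,
    cluster = rep(c(1L, 2L, 3L), needed),
    stringsAsFactors = FALSE)
  panel <- rbind(named, generic)
  panel <- panel[order(panel$cluster, -abs(log(panel$ratio)), panel$name), ]
  ## severity loadings: ten prognostic factors, sign follows effect direction
  prognostic <- c("TfR1", "GDF-15", "Gal-4", "IGFBP-7", "ST2", "TNF-R1",
                  "NT-proBNP", "TNF-R2", "PON3", "TR-AP")
  panel$severity_loading <- ifelse(panel$name %in% prognostic,
                                   0.8 * sign(log(panel$ratio)), 0)
  panel$column <- sprintf("marker_%03d", seq_len(nrow(panel)))
  rownames(panel) <- NULL
  panel[, c("column", "name", "cluster", "ratio", "severity_loading")]
}

#' Default physiology-block specification
#'
#' Per-variable specification for [simulate_physiology()]: category
#' (`physical_capacity`, `daily_activity`, `myocardial_function`), group
#' medians and spreads (medians and interquartile-range-derived standard
#' deviations for the heart-failure and control groups), the loading of the
#' variable on its category's latent factor, and the orientation (`+1` when a
#' larger value means better function, `-1` otherwise).
#'
#' `e_over_e` (the E/E' ratio) is generated but excluded from the canonical
#' 14-variable combined block (`in_combined = FALSE`), matching the variable
#' list used for the physiological principal-component summary.
#'
#' @return A data.frame with one row per physiology variable.
#' @export
default_physiology_spec <- function() {
  spec <- data.frame(
    variable = c("vo2peak", "map", "heart_rate",
                 "pct_active", "pct_inactive", "skewness",
                 "lvef", "psv", "septal_e", "lateral_e", "tapse",
                 "pa_pressure", "la_area", "lvedd", "e_over_e"),
    category = c(rep("physical_capacity", 3), rep("daily_activity", 3),
                 rep("myocardial_function", 9)),
    loc_hf   = c(13.4, 89.2, 72.5, 22, 78, 1.6,
                 25, 0.04, 0.04, 0.05, 15, 47, 31, 64, 16.4),
    loc_ctrl = c(23.8, 106.7, 72, 38, 62, 1.0,
                 57.75, 0.07, 0.07, 0.08, 23, 30, 19, 46, 9.5),
    sd_hf    = c(3.04, 11.8, 11.3, 9.6, 9.6, 1.26,
                 8.9, 0.015, 0.0074, 0.0297, 4.8, 9.6, 7.4, 9.0, 8.4),
    sd_ctrl  = c(5.71, 7.0, 6.7, 9.6, 9.6, 0.52,
                 3.7, 0.015, 0.0148, 0.0297, 5.2, 7.4, 4.2, 7.4, 3.1),
    loading  = c(0.985, 0.985, 0.64, 0.985, 0.985, 0.41,
                 0.985, 0.985, 0.985, 0.81, 0.76, 0.70, 0.64, 0.58, 0.70),
    orientation = c(1, 1, -1, 1, -1, -1,
                    1, 1, 1, 1, 1, -1, -1, -1, -1),
    in_combined = c(rep(TRUE, 14), FALSE),
    stringsAsFactors = FALSE)
  spec
}

#' Default mapping of physiology variables to categories
#'
#' The three clinical-variable blocks used for category summary scores:
#' physical capacity (peak oxygen uptake, mean arterial pressure, heart
#' rate), daily physical activity (percent time active/inactive, cpm
#' skewness) and myocardial function (the echocardiographic block).
#'
#' @return Named list of character vectors of column names.
#' @export
default_category_map <- function() {
  spec <- default_physiology_spec()
  spec <- spec[spec$in_combined, ]
  split(spec$variable, spec$category)
}

#' Default variable orientations
#'
#' Named vector of +1/-1 per physiology variable: +1 when a larger value
#' reflects better function (e.g. peak VO2, LVEF), -1 otherwise (e.g.
#' pulmonary artery pressure, percent time inactive). Used to orient
#' principal-component summary scores so that a higher score always means
#' better function.
#'
#' @return Named numeric vector.
#' @export
default_orientation <- function() {
  spec <- default_physiology_spec()
  setNames(spec$orientation, spec$variable)
}
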