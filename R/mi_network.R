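## Mutual-information network inference: rank-based equal-frequency binned
## MI, permutation significance, data-processing-inequality pruning,
## bootstrap correlation filtering, connectivity analysis and export.

#' Equal-frequency bin assignment on copula ranks
#'
#' Ranks (stable tie-breaking by original order) are mapped to
#' `floor((rank - 1) * bins / n)`, giving bin sizes that differ by at most
#' one. This makes the MI estimate exactly invariant under strictly
#' monotone transforms.
#'
#' @param x Numeric vector.
#' @param bins Number of bins.
#' @return Integer vector of 0-based bin indices.
#' @keywords internal
bin_ranks <- function(x, bins) {
  n <- length(x)
  r <- rank(x, ties.method = "first")
  as.integer(floor((r - 1) * bins / n))
}

default_bins <- function(n) max(3L, min(10L, as.integer(round(n^(1 / 3)))))

#' Mutual information between two variables
#'
#' Plug-in mutual information (nats) of the joint histogram after
#' rank-transforming each variable and discretising into equal-frequency
#' bins (`clamp(round(n^(1/3)), 3, 10)` by default). Non-negative,
#' symmetric, and exactly invariant to strictly monotone transforms of
#' either argument.
#'
#' @param x,y Equal-length numeric vectors (n >= 20).
#' @param bins Number of bins (default from n).
#' @return MI in nats.
#' @export
mutual_info <- function(x, y, bins = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 20) stop("need at least 20 observations")
  if (is.null(bins)) bins <- default_bins(n)
  bx <- bin_ranks(x, bins); by <- bin_ranks(y, bins)
  joint <- base::table(factor(bx, levels = 0:(bins - 1)),
                       factor(by, levels = 0:(bins - 1)))
  pj <- joint / n
  px <- rowSums(pj); py <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / outer(px, py)[nz]))
}

#' Permutation test for mutual information
#'
#' `p = (1 + #[MI_perm >= MI_obs]) / (B + 1)` with a seeded permutation
#' stream, so a fixed seed gives identical p-values across runs.
#'
#' @param x,y Equal-length numeric vectors.
#' @param B Number of permutations (>= 100).
#' @param seed Integer seed for the permutation stream.
#' @param bins Number of bins (default from n).
#' @return List: `mi`, `p`, `B`.
#' @export
mi_permutation_test <- function(x, y, B = 1000, seed = 1, bins = NULL) {
  if (B < 100) stop("B must be at least 100")
  n <- length(x)
  if (is.null(bins)) bins <- default_bins(n)
  bx <- bin_ranks(x, bins); by <- bin_ranks(y, bins)
  res <- .mi_perm_all_cpp(cbind(bx, by), bins, as.integer(B),
                          as.double(seed))
  list(mi = res$mi[1, 2], p = res$p[1, 2], B = B)
}

#' All-pairs candidate edges by MI and permutation FDR
#'
#' Tests every variable pair with the binned MI permutation test and
#' applies Benjamini-Hochberg across all pairs; candidates are pairs with
#' `q < fdr`.
#'
#' @param data Numeric matrix with named columns (>= 3).
#' @param B Permutations per pair.
#' @param seed Seed for the permutation streams.
#' @param fdr Candidate threshold on the BH q-value.
#' @param bins Bin count (default from n).
#' @return Data frame: `node_a`, `node_b`, `mi`, `perm_p`, `bh_q`,
#'   `candidate`.
#' @export
infer_candidate_edges <- function(data, B = 1000, seed = 1, fdr = 0.05,
                                  bins = NULL) {
  data <- as.matrix(data)
  K <- ncol(data)
  if (K < 3) stop("need at least 3 variables")
  n <- nrow(data)
  if (is.null(bins)) bins <- default_bins(n)
  binmat <- vapply(seq_len(K), function(j) bin_ranks(data[, j], bins),
                   integer(n))
  res <- .mi_perm_all_cpp(binmat, bins, as.integer(B), as.double(seed))
  iu <- which(upper.tri(res$mi), arr.ind = TRUE)
  nm <- colnames(data) %||% paste0("V", seq_len(K))
  edges <- data.frame(node_a = nm[iu[, 1]], node_b = nm[iu[, 2]],
                      mi = res$mi[iu], perm_p = res$p[iu],
                      stringsAsFactors = FALSE)
  edges$bh_q <- bh_fdr(edges$perm_p)
  edges$candidate <- edges$bh_q < fdr
  edges
}

#' Data-processing-inequality pruning
#'
#' For every triangle of candidate edges, the weakest edge is marked as
#' indirect and removed when its MI is below `(1 - tolerance)` times the
#' smaller of the other two MI values. Removal decisions are evaluated
#' simultaneously on the original MI values (not sequentially), the ARACNE
#' convention.
#'
#' @param edges Edge data frame from [infer_candidate_edges()].
#' @param tolerance DPI tolerance in \[0, 1\) (default 0.15).
#' @return `edges` with logical column `dpi_removed` added (only candidate
#'   edges can be flagged).
#' @export
apply_dpi <- function(edges, tolerance = 0.15) {
  if (tolerance < 0 || tolerance >= 1) stop("tolerance must be in [0, 1)")
  cand <- which(edges$candidate)
  edges$dpi_removed <- FALSE
  if (length(cand) < 3) return(edges)
  nodes <- unique(c(edges$node_a[cand], edges$node_b[cand]))
  idx <- matrix(NA_integer_, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in cand) {
    idx[edges$node_a[e], edges$node_b[e]] <- e
    idx[edges$node_b[e], edges$node_a[e]] <- e
  }
  remove_flag <- logical(nrow(edges))
  for (e in cand) {
    a <- edges$node_a[e]; b <- edges$node_b[e]
    nbrs <- nodes[!is.na(idx[a, ]) & !is.na(idx[b, ])]
    for (k in nbrs) {
      e_ak <- idx[a, k]; e_bk <- idx[b, k]
      mis <- c(edges$mi[e], edges$mi[e_ak], edges$mi[e_bk])
      weakest <- which.min(mis)
      if (mis[weakest] < min(mis[-weakest]) * (1 - tolerance))
        remove_flag[c(e, e_ak, e_bk)[weakest]] <- TRUE
    }
  }
  edges$dpi_removed <- remove_flag
  edges
}

#' Bootstrap correlation filter
#'
#' For each edge surviving the FDR and DPI stages: Pearson correlation,
#' percentile bootstrap 95% confidence interval (resampling subjects),
#' correlation-test p-value, BH across surviving edges. An edge is
#' retained when `|r| > r_threshold` and `q < fdr`.
#'
#' @param edges Edge data frame (after [apply_dpi()]).
#' @param data The matrix the edges were inferred from.
#' @param B Bootstrap replicates.
#' @param seed RNG seed.
#' @param r_threshold Absolute-correlation retention threshold.
#' @param fdr FDR threshold for the correlation test.
#' @return `edges` with columns `pearson_r`, `r_lo`, `r_hi`, `corr_p`,
#'   `corr_q`, `retained`, `removal_reason`.
#' @export
bootstrap_corr_filter <- function(edges, data, B = 1000, seed = 1,
                                  r_threshold = 0.2, fdr = 0.05) {
  data <- as.matrix(data)
  n <- nrow(data)
  set.seed(seed)
  surv <- which(edges$candidate & !edges$dpi_removed)
  edges$pearson_r <- NA_real_
  edges$r_lo <- NA_real_; edges$r_hi <- NA_real_
  edges$corr_p <- NA_real_; edges$corr_q <- NA_real_
  edges$retained <- FALSE
  if (length(surv)) {
    ia <- match(edges$node_a[surv], colnames(data))
    ib <- match(edges$node_b[surv], colnames(data))
    r_obs <- vapply(seq_along(surv), function(k)
      cor(data[, ia[k]], data[, ib[k]]), numeric(1))
    tstat <- r_obs * sqrt((n - 2) / pmax(1 - r_obs^2, 1e-300))
    p_r <- 2 * pt(-abs(tstat), df = n - 2)
    boot <- matrix(NA_real_, B, length(surv))
    for (bb in seq_len(B)) {
      ridx <- sample.int(n, n, replace = TRUE)
      Xc <- scale(data[ridx, , drop = FALSE])
      boot[bb, ] <- colSums(Xc[, ia, drop = FALSE] *
                              Xc[, ib, drop = FALSE]) / (n - 1)
    }
    lo <- apply(boot, 2, quantile, 0.025, na.rm = TRUE)
    hi <- apply(boot, 2, quantile, 0.975, na.rm = TRUE)
    q_r <- bh_fdr(p_r)
    edges$pearson_r[surv] <- r_obs
    edges$r_lo[surv] <- lo; edges$r_hi[surv] <- hi
    edges$corr_p[surv] <- p_r; edges$corr_q[surv] <- q_r
    edges$retained[surv] <- abs(r_obs) > r_threshold & q_r < fdr
  }
  edges$removal_reason <- ifelse(edges$retained, "none",
    ifelse(!edges$candidate, "fdr",
      ifelse(edges$dpi_removed, "dpi", "corr_filter")))
  edges
}

#' Build the biomarker-physiology MI network
#'
#' Full inference chain on a matrix of marker columns plus the six
#' category PC score columns: all-pairs MI with permutation FDR,
#' DPI pruning, bootstrap correlation filter.
#'
#' @param data Numeric matrix: marker columns + category score columns.
#' @param node_types Named character vector (`"marker"`/`"category"`) per
#'   column; defaults to `"category"` for columns ending in `_PC1`/`_PC2`.
#' @param B_perm,B_boot Permutation / bootstrap counts.
#' @param seed Master seed.
#' @param fdr FDR threshold (both stages).
#' @param r_threshold Correlation retention threshold.
#' @param dpi_tolerance DPI tolerance.
#' @return Object of class `mi_network`: `nodes` (name, type), `edges`.
#' @export
build_mi_network <- function(data, node_types = NULL, B_perm = 1000,
                             B_boot = 1000, seed = 1, fdr = 0.05,
                             r_threshold = 0.2, dpi_tolerance = 0.15) {
  data <- as.matrix(data)
  nm <- colnames(data)
  if (is.null(nm)) stop("data must have column names")
  if (is.null(node_types)) {
    node_types <- ifelse(grepl("_PC[12]$", nm), "category", "marker")
    names(node_types) <- nm
  }
  edges <- infer_candidate_edges(data, B = B_perm, seed = seed, fdr = fdr)
  edges <- apply_dpi(edges, tolerance = dpi_tolerance)
  edges <- bootstrap_corr_filter(edges, data, B = B_boot,
                                 seed = seed + 1L,
                                 r_threshold = r_threshold, fdr = fdr)
  structure(list(nodes = data.frame(name = nm,
                                    type = unname(node_types[nm]),
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 params = list(B_perm = B_perm, B_boot = B_boot,
                               seed = seed, fdr = fdr,
                               r_threshold = r_threshold,
                               dpi_tolerance = dpi_tolerance)),
            class = "mi_network")
}

#' @export
print.mi_network <- function(x, ...) {
  cat("mi_network:", nrow(x$nodes), "nodes;",
      sum(x$edges$retained), "retained /", nrow(x$edges), "tested edges\n")
  invisible(x)
}

#' Connectivity report: category links and key factors
#'
#' A factor links to a clinical category when it retains an edge to either
#' of that category's two PC score nodes; key factors link to all three
#' categories. Edges among category score nodes themselves are excluded
#' from factor degrees.
#'
#' @param network An `mi_network`.
#' @return Object of class `connectivity_report`: `factors` (per-marker
#'   degree, categories linked, key flag), `key_factors`, `n_nodes`,
#'   `n_edges` (retained edges among factors and categories).
#' @export
connectivity_summary <- function(network) {
  nodes <- network$nodes
  edges <- network$edges[network$edges$retained, , drop = FALSE]
  type_of <- setNames(nodes$type, nodes$name)
  markers <- nodes$name[nodes$type == "marker"]
  cat_nodes <- nodes$name[nodes$type == "category"]
  cat_of <- sub("_PC[12]$", "", cat_nodes)
  names(cat_of) <- cat_nodes
  per <- lapply(markers, function(mk) {
    inc <- edges$node_a == mk | edges$node_b == mk
    other <- ifelse(edges$node_a[inc] == mk, edges$node_b[inc],
                    edges$node_a[inc])
    cats <- unique(unname(cat_of[other[other %in% cat_nodes]]))
    data.frame(factor = mk, degree = sum(inc),
               n_categories = length(cats),
               categories = paste(sort(cats), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  factors <- do.call(rbind, per)
  n_cat_total <- length(unique(unname(cat_of)))
  factors$key_factor <- factors$n_categories == n_cat_total &
    n_cat_total > 0
  both_cat <- type_of[edges$node_a] == "category" &
    type_of[edges$node_b] == "category"
  structure(list(factors = factors,
                 key_factors = factors$factor[factors$key_factor],
                 connected_factors =
                   factors$factor[factors$degree > 0],
                 n_nodes = sum(factors$degree > 0) + length(cat_nodes),
                 n_edges = nrow(edges),
                 n_factor_edges = sum(!both_cat)),
            class = "connectivity_report")
}

#' @export
print.connectivity_report <- function(x, ...) {
  cat("connectivity_report:", length(x$connected_factors),
      "connected factors,", x$n_edges, "retained edges,",
      length(x$key_factors), "key factors\n")
  invisible(x)
}

#' Export a network as GraphML and a TSV edge list
#'
#' GraphML carries node `type` attributes and edge attributes (`mi`, `r`,
#' `q`, `retained`); the TSV mirrors the full edge table. The GraphML file
#' round-trips through standard readers.
#'
#' @param network An `mi_network`.
#' @param path Output path without extension; writes `<path>.graphml` and
#'   `<path>_edges.tsv`.
#' @param retained_only Export only retained edges to GraphML (default
#'   TRUE; the TSV always contains all tested pairs).
#' @return Invisibly, the two paths.
#' @export
export_graph <- function(network, path, retained_only = TRUE) {
  edges <- network$edges
  gml <- paste0(path, ".graphml")
  tsv <- paste0(path, "_edges.tsv")
  sel <- if (retained_only) edges$retained else rep(TRUE, nrow(edges))
  edf <- edges[sel, c("node_a", "node_b", "mi", "perm_p", "bh_q",
                      "pearson_r", "corr_q", "retained"), drop = FALSE]
  g <- igraph::graph_from_data_frame(
    edf, directed = FALSE,
    vertices = network$nodes)
  igraph::write_graph(g, gml, format = "graphml")
  write.table(edges, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(graphml = gml, edges = tsv))
}
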