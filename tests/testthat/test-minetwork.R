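test_that("MI equals the brute-force discrete formula and basic identities", {
  set.seed(51)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    b <- max(3L, min(10L, as.integer(round(n^(1 / 3)))))
    expect_equal(mutual_info(x, y), oracle_mi(x, y, b), tolerance = 1e-12)
    ## symmetry and non-negativity
    expect_equal(mutual_info(x, y), mutual_info(y, x), tolerance = 1e-12)
    expect_gte(mutual_info(x, y), 0)
    ## C++ path agrees with the R path
    expect_equal(mi_permutation_test(x, y, B = 100, seed = 1)$mi,
                 mutual_info(x, y), tolerance = 1e-12)
  }

  ## perfect monotone dependence with n divisible by b: MI = log b
  x <- rnorm(60)
  expect_equal(mutual_info(x, x, bins = 4), log(4), tolerance = 1e-12)
  expect_equal(mutual_info(x, exp(x), bins = 4), log(4), tolerance = 1e-12)
})

test_that("MI is exactly invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rnorm(80); y <- x^2 + rnorm(80, sd = 0.3)
  base <- mutual_info(x, y)
  expect_identical(mutual_info(exp(x), y), base)
  expect_identical(mutual_info(x, y^3 + 5), base)
  expect_identical(mutual_info(-1 / (1 + exp(-x)), y), base)
})

test_that("permutation test: determinism, floor p, type-I behaviour, nonlinear power", {
  set.seed(53)
  x <- rnorm(100); y <- rnorm(100)
  r1 <- mi_permutation_test(x, y, B = 500, seed = 9)
  r2 <- mi_permutation_test(x, y, B = 500, seed = 9)
  expect_identical(r1$p, r2$p)
  r3 <- mi_permutation_test(x, y, B = 500, seed = 10)
  ## a different seed may move p slightly but the MI is unchanged
  expect_identical(r1$mi, r3$mi)

  ## perfect dependence: minimum attainable p
  xp <- rnorm(100)
  expect_equal(mi_permutation_test(xp, xp, B = 500, seed = 1)$p, 1 / 501)

  ## nonlinear (V-shaped) dependence with near-zero Pearson correlation
  set.seed(54)
  u <- runif(500)
  v <- abs(u - 0.5)
  expect_lt(abs(cor(u, v)), 0.15)
  expect_lt(mi_permutation_test(u, v, B = 500, seed = 2)$p, 0.01)
})

test_that("candidate edges: null panel controlled, planted chain found, deterministic", {
  set.seed(55)
  X0 <- matrix(rnorm(80 * 8), 80, 8,
               dimnames = list(NULL, paste0("v", 1:8)))
  e0 <- infer_candidate_edges(X0, B = 300, seed = 3)
  expect_lte(mean(e0$candidate), 0.05)
  expect_equal(nrow(e0), choose(8, 2))

  ## planted chain A - B - C: AB and BC are candidates before DPI
  set.seed(56)
  n <- 1000
  A <- rnorm(n); B <- A + rnorm(n, sd = 0.6); C <- B + rnorm(n, sd = 0.6)
  dat <- cbind(A = A, B = B, C = C,
               N1 = rnorm(n), N2 = rnorm(n))
  e1 <- infer_candidate_edges(dat, B = 300, seed = 4)
  key <- function(a, b) which((e1$node_a == a & e1$node_b == b) |
                                (e1$node_a == b & e1$node_b == a))
  expect_true(e1$candidate[key("A", "B")])
  expect_true(e1$candidate[key("B", "C")])

  e1b <- infer_candidate_edges(dat, B = 300, seed = 4)
  expect_identical(e1, e1b)
})

test_that("DPI rule arithmetic on constructed triangles", {
  mk_edges <- function(mis) {
    data.frame(node_a = c("A", "A", "B"), node_b = c("B", "C", "C"),
               mi = mis, perm_p = 0.001, bh_q = 0.001, candidate = TRUE,
               stringsAsFactors = FALSE)
  }
  ## weakest edge clearly indirect: removed at tolerance 0
  e <- apply_dpi(mk_edges(c(0.5, 0.4, 0.1)), tolerance = 0)
  expect_equal(e$dpi_removed, c(FALSE, FALSE, TRUE))
  ## within tolerance: all kept (0.38 >= 0.4 * 0.85)
  e2 <- apply_dpi(mk_edges(c(0.5, 0.4, 0.38)), tolerance = 0.15)
  expect_false(any(e2$dpi_removed))
  ## just below tolerance: removed (0.33 < 0.4 * 0.85)
  e3 <- apply_dpi(mk_edges(c(0.5, 0.4, 0.33)), tolerance = 0.15)
  expect_equal(e3$dpi_removed, c(FALSE, FALSE, TRUE))
  ## non-candidate edges cannot form triangles
  e4 <- mk_edges(c(0.5, 0.4, 0.1)); e4$candidate[1] <- FALSE
  expect_false(any(apply_dpi(e4, tolerance = 0)$dpi_removed))
})

test_that("DPI removals are simultaneous, not sequential", {
  ## triangle ABC removes A-C (0.2 < min(0.5, 0.45)); triangle ACD removes
  ## C-D (0.18 < min(0.2, 0.5)). A sequential scheme that first deleted
  ## A-C would break triangle ACD and let C-D survive; simultaneous
  ## evaluation on the original MI values removes both.
  e <- data.frame(
    node_a = c("A", "B", "A", "C", "A"),
    node_b = c("B", "C", "C", "D", "D"),
    mi = c(0.5, 0.45, 0.20, 0.18, 0.5),
    perm_p = 0.001, bh_q = 0.001, candidate = TRUE,
    stringsAsFactors = FALSE)
  out <- apply_dpi(e, tolerance = 0)
  expect_equal(out$dpi_removed, c(FALSE, FALSE, TRUE, TRUE, FALSE))
})

test_that("filter chain is monotone and the correlation filter enforces |r| > 0.2", {
  set.seed(57)
  n <- 400
  ## x3 depends on x1 through a noisy channel tuned to |r| ~ 0.15
  x1 <- rnorm(n)
  dat <- cbind(a = x1, b = x1 + rnorm(n, sd = 0.5),
               c = 0.15 * x1 + rnorm(n) * sqrt(1 - 0.15^2),
               d = rnorm(n))
  net <- build_mi_network(dat, node_types = setNames(rep("marker", 4),
                                                     colnames(dat)),
                          B_perm = 500, B_boot = 300, seed = 5)
  e <- net$edges
  ## monotone: retained subset of DPI-pass subset of candidates
  expect_true(all(!e$retained | (e$candidate & !e$dpi_removed)))
  ab <- e$retained[(e$node_a == "a" & e$node_b == "b")]
  expect_true(ab)
  ## the weak-correlation pair is never retained even if its MI is
  ## significant
  ac <- which(e$node_a == "a" & e$node_b == "c")
  if (e$candidate[ac] && !e$dpi_removed[ac])
    expect_true(abs(e$pearson_r[ac]) <= 0.2 || !e$retained[ac])
  expect_true(all(abs(e$pearson_r[e$retained]) > 0.2))
  expect_true(all(e$bh_q[e$retained] < 0.05))
  expect_true(all(e$removal_reason %in%
                    c("none", "fdr", "dpi", "corr_filter")))
  expect_true(all((e$removal_reason == "none") == e$retained))
})

test_that("connectivity report identifies key factors and empty networks", {
  nodes <- data.frame(
    name = c("m1", "m2", "physical_capacity_PC1", "daily_activity_PC1",
             "myocardial_function_PC1"),
    type = c("marker", "marker", "category", "category", "category"),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    node_a = c("m1", "m1", "m1", "m2"),
    node_b = c("physical_capacity_PC1", "daily_activity_PC1",
               "myocardial_function_PC1", "physical_capacity_PC1"),
    mi = 0.3, perm_p = 0.001, bh_q = 0.001, candidate = TRUE,
    dpi_removed = FALSE, pearson_r = 0.5, r_lo = 0.3, r_hi = 0.7,
    corr_p = 0.001, corr_q = 0.001, retained = TRUE,
    removal_reason = "none", stringsAsFactors = FALSE)
  net <- structure(list(nodes = nodes, edges = edges), class = "mi_network")
  rep <- connectivity_summary(net)
  expect_equal(rep$key_factors, "m1")
  expect_equal(rep$factors$degree[rep$factors$factor == "m1"], 3)
  expect_equal(rep$factors$n_categories[rep$factors$factor == "m2"], 1)

  edges0 <- edges[0, ]
  net0 <- structure(list(nodes = nodes, edges = edges0),
                    class = "mi_network")
  rep0 <- connectivity_summary(net0)
  expect_length(rep0$key_factors, 0)
  expect_equal(rep0$n_edges, 0)
})

test_that("GraphML export round-trips through a standard reader", {
  set.seed(58)
  dat <- matrix(rnorm(100 * 4), 100, 4,
                dimnames = list(NULL, c("a", "b", "c", "d")))
  dat[, 2] <- dat[, 1] + rnorm(100, sd = 0.4)
  net <- build_mi_network(dat, node_types = setNames(rep("marker", 4),
                                                     colnames(dat)),
                          B_perm = 300, B_boot = 200, seed = 6)
  path <- file.path(tempdir(), "toynet")
  out <- export_graph(net, path)
  expect_true(file.exists(out["graphml"]))
  expect_true(file.exists(out["edges"]))
  g <- igraph::read_graph(out["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g), 4)
  expect_equal(igraph::ecount(g), sum(net$edges$retained))
  expect_setequal(igraph::vertex_attr(g, "type"), "marker")
  if (igraph::ecount(g) > 0) {
    expect_equal(sort(igraph::edge_attr(g, "mi")),
                 sort(net$edges$mi[net$edges$retained]),
                 tolerance = 1e-9)
  }
  ## empty network still yields valid GraphML with nodes only
  net0 <- net; net0$edges$retained <- FALSE
  out0 <- export_graph(net0, file.path(tempdir(), "emptynet"))
  g0 <- igraph::read_graph(out0["graphml"], format = "graphml")
  expect_equal(igraph::vcount(g0), 4)
  expect_equal(igraph::ecount(g0), 0)
})

test_that("small-n and bad input guards", {
  expect_error(mutual_info(1:10, 1:10), "at least 20")
  expect_error(mutual_info(1:30, 1:29), "equal length")
  expect_error(mi_permutation_test(rnorm(30), rnorm(30), B = 50), "100")
  expect_error(infer_candidate_edges(matrix(rnorm(40), 20, 2)),
               "at least 3")
  expect_error(apply_dpi(data.frame(candidate = TRUE), tolerance = 1.2),
               "tolerance")
})
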