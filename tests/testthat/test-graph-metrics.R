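test_that("density grid and edge counts follow the proportional rule", {
  d <- density_grid()
  expect_length(d, 25L)
  expect_equal(d[1L], 0.10)
  expect_equal(d[25L], 0.34)
  expect_equal(unique(round(diff(d), 10)), 0.01)

  # N=5: 10 possible edges, density 0.10 keeps exactly the global max
  set.seed(6)
  z <- matrix(rnorm(25), 5); z <- (z + t(z)) / 2; diag(z) <- 0
  g <- binarize_at_density(z, 0.10)
  expect_equal(igraph::ecount(g), 1L)
  el <- igraph::as_edgelist(g)
  up <- which(upper.tri(z), arr.ind = TRUE)
  best <- up[which.max(z[up]), ]
  expect_equal(sort(as.integer(el)), sort(as.integer(best)))

  # N=400 at 34% keeps round(0.34 * 79800) = 27132 edges
  expect_equal(nrow(edge_index(400L)), 79800L)
  z4 <- matrix(0, 400, 400)
  set.seed(7)
  v <- rnorm(79800)
  z4[upper.tri(z4)] <- v
  z4 <- z4 + t(z4)
  expect_equal(igraph::ecount(binarize_at_density(z4, 0.34)), 27132L)

  # all-equal z: ties resolved by ascending lexicographic edge index
  zt <- matrix(1, 5, 5); diag(zt) <- 0
  gt <- binarize_at_density(zt, 0.3)  # keeps 3 of 10 edges
  expect_equal(igraph::as_edgelist(gt),
               matrix(c(1, 1, 1, 2, 3, 4), 3, 2))
  expect_error(binarize_at_density(zt, 0.01), "zero edges")
})

test_that("global and nodal metrics match brute-force oracles on 200 random graphs", {
  set.seed(2024)
  n_checked <- 0L
  for (rep in 1:200) {
    n <- sample(5:12, 1)
    p <- runif(1, 0.2, 0.7)
    a <- random_adjacency(n, p)
    if (sum(a) / 2 < 2) next
    g <- graph_from_adj(a)
    gm <- global_metrics(g)
    expect_equal(gm[["Cp"]], mean(oracle_clustering(a)),
                 tolerance = 1e-12)
    expect_equal(gm[["Eglob"]], oracle_global_efficiency(a),
                 tolerance = 1e-12)
    expect_equal(gm[["Eloc"]], oracle_local_efficiency(a),
                 tolerance = 1e-12)
    lp <- oracle_char_path(a)
    if (is.na(lp)) {
      expect_true(is.na(gm[["Lp"]]))
    } else {
      expect_equal(gm[["Lp"]], lp, tolerance = 1e-12)
    }
    or_as <- oracle_assortativity(a)
    if (is.na(or_as)) {
      expect_true(is.na(gm[["assortativity"]]))
    } else {
      expect_equal(gm[["assortativity"]], or_as, tolerance = 1e-12)
    }
    nm <- nodal_metrics(g)
    expect_equal(unname(nm[, "degree"]), unname(rowSums(a)),
                 tolerance = 1e-12)
    expect_equal(unname(nm[, "betweenness"]), oracle_betweenness(a),
                 tolerance = 1e-12)
    expect_equal(unname(nm[, "efficiency"]),
                 unname(oracle_nodal_efficiency(a)), tolerance = 1e-12)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 190L)
})

test_that("metrics agree with igraph on larger graphs", {
  set.seed(11)
  a <- random_adjacency(60, 0.15)
  g <- graph_from_adj(a)
  gm <- global_metrics(g)
  expect_equal(gm[["Cp"]],
               mean(igraph::transitivity(g, type = "local",
                                         isolates = "zero")),
               tolerance = 1e-12)
  expect_equal(gm[["Eglob"]], igraph::global_efficiency(g),
               tolerance = 1e-12)
  expect_equal(gm[["assortativity"]], igraph::assortativity_degree(g),
               tolerance = 1e-12)
  nm <- nodal_metrics(g)
  expect_equal(unname(nm[, "betweenness"]),
               unname(igraph::betweenness(g, directed = FALSE)),
               tolerance = 1e-10)
})

test_that("canonical graphs give their closed-form metric values", {
  k4 <- graph_from_adj(matrix(1, 4, 4) - diag(4))
  gm <- global_metrics(k4)
  expect_equal(unname(gm[c("Cp", "Lp", "Eglob", "Eloc")]),
               c(1, 1, 1, 1), tolerance = 1e-12)
  nm4 <- nodal_metrics(k4)
  expect_equal(unname(nm4[, "efficiency"]), rep(1, 4), tolerance = 1e-12)

  # path 1-2-3
  p3 <- igraph::make_graph(c(1, 2, 2, 3), directed = FALSE)
  gm3 <- global_metrics(p3)
  expect_equal(gm3[["Lp"]], 4 / 3, tolerance = 1e-12)
  expect_equal(gm3[["Eglob"]], 5 / 6, tolerance = 1e-12)
  nm3 <- nodal_metrics(p3)
  expect_equal(unname(nm3[1, "efficiency"]), (1 + 0.5) / 2,
               tolerance = 1e-12)

  # star K_{1,3}: assortativity -1
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(global_metrics(star)[["assortativity"]], -1,
               tolerance = 1e-12)
  # star K_{1,4} center: degree 4, betweenness C(4,2) = 6
  star5 <- igraph::make_star(5, mode = "undirected", center = 1)
  nms <- nodal_metrics(star5)
  expect_equal(unname(nms[1, "degree"]), 4)
  expect_equal(unname(nms[1, "betweenness"]), 6, tolerance = 1e-12)

  # triangle 1-2-3 plus pendant edge 1-4: Cp = (1/3 + 1 + 1 + 0)/4
  tp <- igraph::make_graph(c(1, 2, 2, 3, 1, 3, 1, 4), directed = FALSE)
  expect_equal(global_metrics(tp)[["Cp"]], 7 / 12, tolerance = 1e-12)
})

test_that("degree-preserving rewiring keeps degrees and is seeded", {
  set.seed(3)
  a <- random_adjacency(20, 0.3)
  g <- graph_from_adj(a)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  set.seed(10)
  r1 <- rewire_edges_cpp(el, 10L * nrow(el))
  set.seed(10)
  r2 <- rewire_edges_cpp(el, 10L * nrow(el))
  expect_identical(r1, r2)
  a2 <- matrix(0, 20, 20)
  a2[r1] <- 1
  a2 <- pmax(a2, t(a2))
  expect_equal(rowSums(a2), rowSums(a))  # degree sequence preserved
  expect_false(isTRUE(all.equal(a2, a)))  # but the wiring changed
  expect_gt(attr(r1, "n_successful_swaps"), 0L)

  # null means are deterministic under a fixed seed
  set.seed(5)
  m1 <- random_null_metrics(g, n_null = 5L)
  set.seed(5)
  m2 <- random_null_metrics(g, n_null = 5L)
  expect_identical(m1, m2)

  # complete K5 admits no swap: null equals observed, gamma = lambda = 1
  k5 <- graph_from_adj(matrix(1, 5, 5) - diag(5))
  set.seed(1)
  nm <- random_null_metrics(k5, n_null = 3L)
  gm <- global_metrics(k5)
  expect_equal(nm[["Cp_rand"]], gm[["Cp"]], tolerance = 1e-12)
  expect_equal(nm[["Lp_rand"]], gm[["Lp"]], tolerance = 1e-12)
})

test_that("AUC over densities matches closed forms", {
  d <- density_grid()
  expect_equal(auc_over_densities(rep(2, 25), d), 0.48,
               tolerance = 1e-12)
  expect_equal(auc_over_densities(d, d), (0.34^2 - 0.10^2) / 2,
               tolerance = 1e-12)
  expect_error(auc_over_densities(1, 0.2), "two finite")
  expect_warning(
    v <- auc_over_densities(c(1, NaN, 1, 1, 1), seq(0.1, 0.5, 0.1)),
    "dropped")
  expect_equal(v, 0.4, tolerance = 1e-12)
})

test_that("metric curves satisfy structural invariants", {
  coh <- small_cohort(n_patients = 2, n_controls = 2, seed = 17)
  z <- build_fc_matrix(coh$timeseries[[1L]])$z
  set.seed(2)
  mc <- metric_curves(z, n_null = 3L)
  # sigma == gamma / lambda to machine precision on every row
  expect_equal(mc$global[, "sigma"],
               mc$global[, "gamma"] / mc$global[, "lambda"],
               tolerance = 1e-15)
  # nested graphs: Eglob non-decreasing in density
  expect_true(all(diff(mc$global[, "Eglob"]) >= 0))
  # node relabeling leaves global metrics untouched
  set.seed(9)
  perm <- sample(14L)
  z2 <- z[perm, perm]
  g1 <- global_metrics(binarize_at_density(z, 0.25))
  g2 <- global_metrics(binarize_at_density(z2, 0.25))
  expect_equal(g1, g2, tolerance = 1e-12)
  # nodal metrics permute along with the labels
  n1 <- nodal_metrics(binarize_at_density(z, 0.25))
  n2 <- nodal_metrics(binarize_at_density(z2, 0.25))
  expect_equal(n2, n1[perm, ], tolerance = 1e-12)
})
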