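test_that("strength normalization yields unit mean weight and scale invariance", {
  set.seed(8)
  w <- matrix(stats::runif(90 * 90), 90, 90)
  w <- w + t(w); diag(w) <- 0
  conn <- connectome(w)
  n1 <- normalize_strength(conn)
  expect_lt(abs(mean(n1$weights[upper.tri(n1$weights)]) - 1), 1e-12)
  conn2 <- conn; conn2$weights <- conn$weights * 7.3
  n2 <- normalize_strength(conn2)
  expect_lt(max(abs(n1$weights - n2$weights)), 1e-12)

  cw <- connectome(matrix(2, 4, 4) - diag(2, 4), labels = letters[1:4])
  expect_true(all(normalize_strength(cw)$weights[upper.tri(diag(4))] == 1))
  expect_error(normalize_strength(connectome(matrix(0, 4, 4),
                                             labels = letters[1:4])),
               "all-zero")
})

test_that("density thresholding keeps the k strongest edges", {
  set.seed(9)
  w <- matrix(stats::runif(90 * 90), 90, 90)
  w <- w + t(w); diag(w) <- 0
  conn <- connectome(w)
  g <- threshold_to_density(conn, 0.06)
  expect_equal(igraph::ecount(g), 240)   # round(0.06 * 90*89/2)
  # sorting oracle: retained edges are exactly the 240 largest weights
  wt <- w[upper.tri(w)]
  cut <- sort(wt, decreasing = TRUE)[240]
  el <- igraph::as_edgelist(g, names = FALSE)
  kept_w <- w[cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))]
  expect_true(all(kept_w >= cut))
  expect_equal(sort(kept_w), sort(wt)[(length(wt) - 239):length(wt)])

  # sparser matrix than requested density: keep all, warn, record density
  sparse <- matrix(0, 90, 90)
  sparse[1, 2:11] <- 1; sparse <- sparse + t(sparse)
  expect_warning(gs <- threshold_to_density(connectome(sparse), 0.06),
                 "keeping all")
  expect_equal(igraph::ecount(gs), 10)
  expect_equal(gs$achieved_density, 10 / 4005)
})

test_that("clustering, path length, and efficiency have known closed forms", {
  K5 <- graph_from_adj(matrix(1, 5, 5) - diag(5))
  cl <- clustering_and_path(K5)
  expect_equal(cl$C, 1)
  expect_equal(cl$L, 1)
  ef <- efficiencies(graph_from_adj(matrix(1, 4, 4) - diag(4)))
  expect_equal(ef$global_efficiency, 1)
  expect_equal(ef$local_efficiency, 1)

  P3 <- matrix(0, 3, 3); P3[1, 2] <- P3[2, 3] <- 1; P3 <- P3 + t(P3)
  cl3 <- clustering_and_path(graph_from_adj(P3))
  expect_equal(cl3$C, 0)
  expect_equal(cl3$L, (1 + 1 + 2) / 3)

  ef0 <- efficiencies(igraph::make_empty_graph(5, directed = FALSE))
  expect_equal(ef0$global_efficiency, 0)
  expect_equal(ef0$local_efficiency, 0)
  expect_error(clustering_and_path(igraph::make_empty_graph(3,
                                                            directed = FALSE)),
               "edgeless")
})

test_that("node metrics match star/regular closed forms", {
  ring <- graph_from_adj({
    A <- matrix(0, 6, 6)
    for (i in 1:6) { A[i, i %% 6 + 1] <- 1 }
    A + t(A)
  })
  nm <- node_metrics(ring)
  expect_true(all(abs(nm$degree_normalized - 1) < 1e-12))

  star <- matrix(0, 6, 6); star[1, 2:6] <- 1; star <- star + t(star)
  nm2 <- node_metrics(graph_from_adj(star))
  expect_equal(unname(nm2$betweenness[1]), 1)
  expect_true(all(nm2$betweenness[-1] == 0))
})

test_that("degree-preserving nulls preserve degrees and are seed-reproducible", {
  set.seed(10)
  A <- random_adjacency(40, 0.15)
  g <- graph_from_adj(A)
  ne <- random_reference(g, n_random = 10, seed = 42)
  for (gr in ne$graphs)
    expect_identical(igraph::degree(gr), igraph::degree(g))
  ne2 <- random_reference(g, n_random = 10, seed = 42)
  expect_equal(ne$c_rand_mean, ne2$c_rand_mean)
  expect_equal(ne$l_rand_mean, ne2$l_rand_mean)
  expect_error(random_reference(igraph::make_empty_graph(3,
                                                         directed = FALSE)),
               "2 edges")
})

test_that("rewiring destroys lattice clustering", {
  # ring lattice: high clustering; degree-preserving randomization lowers it
  hits <- 0L
  for (s in 1:20) {
    g <- igraph::sample_smallworld(1, 60, 4, 0)   # pure lattice
    ne <- random_reference(g, n_random = 3, seed = s)
    C <- clustering_and_path(g)$C
    hits <- hits + (ne$c_rand_mean < C)
  }
  expect_gte(hits, 19)
})

test_that("small-worldness composes its normalized ratios", {
  sw <- small_worldness(0.5, 0.1, 2.2, 2.0)
  expect_equal(sw$sw, 5 / 1.1, tolerance = 1e-12)
  expect_equal(small_worldness(0.3, 0.3, 2, 2)$sw, 1)
  expect_error(small_worldness(0, 1, 1, 1), "positive")
})

test_that("AUC over densities matches rectangle, trapezoid, and fine-sum oracle", {
  grid <- density_grid()
  expect_equal(length(grid), 7)
  expect_equal(auc_over_densities(rep(3, 7), grid), 3 * 0.06 * 100)
  lin <- 2 + 10 * grid
  exact <- 100 * (2 * 0.06 + 10 * (0.12^2 - 0.06^2) / 2)
  expect_equal(auc_over_densities(lin, grid), exact)
  set.seed(5)
  vals <- stats::runif(7)
  expect_equal(auc_over_densities(vals, grid), oracle_auc(vals, grid),
               tolerance = 1e-6)
  expect_error(auc_over_densities(c(1, NA, 1, 1, 1, 1, 1), grid), "missing")
})

test_that("graph metrics agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (r in 1:40) {
    n <- sample(8:30, 1)
    A <- random_adjacency(n, stats::runif(1, 0.12, 0.3))
    if (sum(A) == 0) next
    g <- graph_from_adj(A)
    cl <- clustering_and_path(g)
    expect_equal(cl$C, oracle_clustering(A), tolerance = 1e-12)
    expect_equal(cl$L, oracle_path_length(A), tolerance = 1e-12)
    ef <- efficiencies(g)
    expect_equal(ef$global_efficiency, oracle_global_efficiency(A),
                 tolerance = 1e-12)
    expect_equal(ef$local_efficiency, oracle_local_efficiency(A),
                 tolerance = 1e-12)
    nm <- node_metrics(g)
    expect_equal(unname(nm$degree_normalized),
                 rowSums(A) / mean(rowSums(A)), tolerance = 1e-12)
    expect_equal(unname(nm$betweenness), oracle_betweenness(A),
                 tolerance = 1e-9)
  }
})

test_that("small-world generative graphs score SW > 1", {
  set.seed(123)
  for (r in 1:5) {
    g <- igraph::sample_smallworld(1, 90, 6, 0.1)
    g <- igraph::simplify(g)
    cl <- clustering_and_path(g)
    ne <- random_reference(g, n_random = 10, seed = r)
    sw <- small_worldness(cl$C, ne$c_rand_mean, cl$L, ne$l_rand_mean)
    expect_gt(sw$sw, 1)
  }
})

test_that("group-by-time network analysis flags designed node changes after FDR", {
  cfg <- cohort_config(n_patients = 10, n_controls = 10, seed = 61)
  sim <- generate_cohort(cfg)
  conns <- generate_connectomes(cfg, sim$subjects)
  groups <- stats::setNames(sim$subjects$group, sim$subjects$subject_id)
  auc_df <- cohort_network_auc(conns, groups, n_random = 5, seed = 61)
  res <- network_group_analysis(auc_df)
  deg <- res$nodes[res$nodes$metric == "node_degree", ]
  expect_true(all(c("thalamus_l", "thalamus_r") %in%
                    deg$node[deg$significant]))
  # BH adjustment equals the step-up rule applied directly
  p <- deg$p
  n <- length(p)
  o <- order(p)
  stepup <- numeric(n)
  stepup[o] <- rev(cummin(rev(p[o] * n / seq_len(n))))
  expect_equal(deg$p_fdr, pmin(1, stepup), tolerance = 1e-12)
})
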