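test_that("closed-form fixtures are reproduced exactly", {
  k4 <- graph_k4()
  cc <- clustering_coefficient(k4)
  expect_equal(cc$cp, 1)
  expect_equal(unname(cc$c_i), rep(1, 4))
  expect_equal(characteristic_path_length(k4), 1)

  expect_equal(clustering_coefficient(graph_path(6))$cp, 0)
  expect_equal(characteristic_path_length(graph_cycle(5)), 1.5)

  # triangle with a pendant: C = (1/3, 1, 1, 0)
  tri <- matrix(0, 4, 4)
  tri[1, 2] <- tri[2, 3] <- tri[1, 3] <- tri[1, 4] <- 1
  tri <- tri + t(tri)
  cc2 <- clustering_coefficient(tri)
  expect_equal(unname(cc2$c_i), c(1 / 3, 1, 1, 0))
  expect_equal(cc2$cp, 7 / 12)

  star <- graph_star(4)
  bc <- betweenness_centrality(star)
  expect_equal(bc$betweenness, c(6, 0, 0, 0, 0))
  expect_equal(bc$b, c(5, 0, 0, 0, 0))

  # 4-cycle: opposite pairs split over two routes, all B = 0.5, b = 1
  bc4 <- betweenness_centrality(graph_cycle(4))
  expect_equal(bc4$betweenness, rep(0.5, 4))
  expect_equal(bc4$b, rep(1, 4))
})

test_that("metrics match brute-force oracles on enumerated small graphs", {
  # exhaustive labelled connected graphs at N = 4 and a sample at N = 5
  for (n in 4:5) {
    n_pairs <- n * (n - 1) / 2
    masks <- if (n == 4) 0:(2^n_pairs - 1) else {
      set.seed(50)
      sample(0:(2^n_pairs - 1), 300)
    }
    checked <- 0
    for (mask in masks) {
      adj <- adj_from_bitmask(n, mask)
      if (!oracle_connected(adj)) next
      checked <- checked + 1
      expect_equal(clustering_coefficient(adj)$c_i,
                   oracle_clustering(adj)$c_i, tolerance = 1e-12)
      expect_equal(characteristic_path_length(adj), oracle_lp(adj),
                   tolerance = 1e-12)
      expect_equal(suppressWarnings(betweenness_centrality(adj))$betweenness,
                   oracle_betweenness(adj), tolerance = 1e-12)
    }
    # 38 connected labelled graphs exist at N = 4 (exhaustive); the N = 5
    # sample should cover well over 100
    expect_gte(checked, if (n == 4) 38 else 100)
  }
})

test_that("distance computation matches Floyd-Warshall on random graphs", {
  set.seed(60)
  for (rep in 1:5) {
    adj <- random_connected_graph(15, 0.25)
    expect_equal(metabnet:::mn_dist_matrix(adj), oracle_distances(adj))
  }
})

test_that("strict mode refuses disconnected graphs", {
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- 1
  expect_error(characteristic_path_length(adj), "disconnected")
  expect_true(is.na(characteristic_path_length(adj, strict = FALSE)))
})

test_that("node relabelling permutes per-node metrics equivariantly", {
  set.seed(70)
  for (rep in 1:5) {
    adj <- random_connected_graph(12, 0.3)
    perm <- sample(12)
    padj <- adj[perm, perm]
    expect_equal(clustering_coefficient(padj)$c_i,
                 clustering_coefficient(adj)$c_i[perm])
    expect_equal(betweenness_centrality(padj)$betweenness,
                 betweenness_centrality(adj)$betweenness[perm],
                 tolerance = 1e-9)
    expect_equal(characteristic_path_length(padj),
                 characteristic_path_length(adj))
    expect_equal(clustering_coefficient(padj)$cp,
                 clustering_coefficient(adj)$cp)
  }
})

test_that("adding an edge never increases the path length", {
  set.seed(80)
  for (rep in 1:10) {
    adj <- random_connected_graph(12, 0.25)
    open <- which(adj == 0 & upper.tri(adj), arr.ind = TRUE)
    if (nrow(open) == 0) next
    pick <- open[sample(nrow(open), 1), ]
    adj2 <- adj
    adj2[pick[1], pick[2]] <- adj2[pick[2], pick[1]] <- 1
    expect_lte(characteristic_path_length(adj2),
               characteristic_path_length(adj))
  }
})

test_that("normalized betweenness has unit mean when any B > 0", {
  set.seed(90)
  for (rep in 1:5) {
    adj <- random_connected_graph(14, 0.3)
    bc <- betweenness_centrality(adj)
    if (all(bc$betweenness == 0)) next
    expect_equal(mean(bc$b), 1, tolerance = 1e-12)
  }
  expect_warning(bk4 <- betweenness_centrality(graph_k4()), "zero")
  expect_equal(bk4$b, rep(0, 4))
})

test_that("random references preserve the degree sequence", {
  set.seed(100)
  adj <- random_connected_graph(20, 0.25)
  refs <- random_reference(adj, n_random = 10, seed = 1)
  for (ref in refs) {
    expect_equal(rowSums(ref), rowSums(adj))
    expect_true(oracle_connected(ref))
    expect_true(isSymmetric(ref))
    expect_equal(unname(diag(ref)), rep(0, 20))
  }
  # degree-2-everywhere 4-cycle is rigid up to isomorphism
  refs4 <- random_reference(graph_cycle(4), n_random = 5, seed = 2)
  for (ref in refs4) {
    expect_equal(unname(rowSums(ref)), rep(2, 4))
    expect_true(oracle_connected(ref))
  }
})

test_that("rewiring destroys lattice clustering", {
  lattice <- metabnet:::mn_ring_lattice(90, 5)
  cp_lattice <- clustering_coefficient(lattice)$cp
  refs <- random_reference(lattice, n_random = 20, seed = 3)
  cp_rand <- mean(vapply(refs, function(a) clustering_coefficient(a)$cp,
                         numeric(1)))
  expect_gt(cp_lattice, 2 * cp_rand)
})

test_that("sigma equals gamma over lambda and self-reference is ~1", {
  set.seed(110)
  ws <- metabnet:::mn_watts_strogatz(60, 4, 0.1)
  sw <- small_world(ws, n_random = 20, seed = 4)
  expect_equal(sw$sigma, sw$gamma / sw$lambda, tolerance = 1e-12)
  expect_gt(sw$gamma, 1)
})

test_that("hub classification applies the threshold and sorts by region", {
  cyc <- graph_cycle(6)
  dimnames(cyc) <- list(paste0("R", 1:6), paste0("R", 1:6))
  hubs <- classify_hubs(cyc, threshold = 1.5)
  expect_false(any(hubs$hub)) # all b_i = 1 on a cycle
  star <- graph_star(4)
  dimnames(star) <- list(paste0("N", 1:5), paste0("N", 1:5))
  hs <- classify_hubs(star, threshold = 1.5, group = "g")
  expect_identical(hs$region[hs$hub], "N1")
  expect_equal(hs$b[1], 5)
  # threshold 2.0 variant
  expect_identical(classify_hubs(star, threshold = 2)$region[
    classify_hubs(star, threshold = 2)$hub], "N1")
})

test_that("shared hubs equal the set intersection", {
  t1 <- tibble::tibble(region = c("A", "B", "C", "D"),
                       b = c(3, 2, 1, 0.5),
                       hub = c(TRUE, TRUE, FALSE, FALSE), group = "g1")
  t2 <- tibble::tibble(region = c("A", "B", "C", "D"),
                       b = c(2.5, 0.4, 1.9, 3),
                       hub = c(TRUE, FALSE, TRUE, TRUE), group = "g2")
  sh <- shared_hubs(t1, t2)
  expect_identical(sh$region,
                   intersect(t1$region[t1$hub], t2$region[t2$hub]))
  expect_equal(sh$b_g1, 3)
  expect_equal(sh$b_g2, 2.5)
})

test_that("metric curves run the full chain per group", {
  co <- generate_cohort(cohort_spec(n_per_group = 20, n_regions = 24,
                                    seed = 12))
  res <- residualize(normalize_whole_brain(co))
  cv <- metric_curves(res, densities = c(0.2, 0.3), n_random = 5,
                      seed = 9)
  expect_setequal(unique(cv$metric), c("cp", "lp", "gamma", "lambda",
                                       "sigma"))
  expect_equal(nrow(cv), 2 * 2 * 5)
  # cp/lp agree with direct computation
  net <- correlation_network(res, "control")
  bn <- threshold_by_density(net, 0.2)
  expect_equal(cv$value[cv$group == "control" & cv$density == 0.2 &
                          cv$metric == "cp"],
               clustering_coefficient(bn)$cp)
})
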