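make_residuals <- function(m, group = rep(c("control", "patient"),
                                          each = nrow(m) / 2)) {
  if (is.null(colnames(m))) colnames(m) <- paste0("R", seq_len(ncol(m)))
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = sprintf("S%02d", seq_len(nrow(m))),
                   group = group),
    tibble::as_tibble(m))
  structure(out, region_names = colnames(m),
            class = c("metab_residuals", class(out)))
}

test_that("correlation networks reproduce hand-computed Pearson values", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), dup = c(1, 2, 3, 4),
             neg = -c(1, 2, 3, 4))
  res <- make_residuals(rbind(m, m), group = rep(c("g1", "g2"), each = 4))
  net <- correlation_network(res, "g1")
  expect_equal(net$r["a", "b"], 0.8)
  expect_equal(net$r["a", "dup"], 1)
  expect_equal(net$r["a", "neg"], -1)
  expect_equal(net$n_subjects, 4)
  expect_true(isSymmetric(net$r))
  expect_equal(unname(diag(net$r)), rep(1, 4))
})

test_that("correlation networks reject tiny or degenerate groups", {
  m <- matrix(rnorm(8), 4, 2)
  res <- make_residuals(m, group = c("g1", "g1", "g1", "g2"))
  expect_error(correlation_network(res, "g2"), "fewer than 3")
  m2 <- cbind(rnorm(6), 0)
  res2 <- make_residuals(m2, group = rep("g1", 6))
  expect_error(correlation_network(res2, "g1"), "R2")
})

test_that("correlation is invariant to per-region affine rescaling", {
  set.seed(10)
  m <- matrix(rnorm(60), 10, 6)
  res1 <- make_residuals(m, group = rep("g", 10))
  m2 <- sweep(sweep(m, 2, runif(6, 0.5, 3), "*"), 2, rnorm(6), "+")
  res2 <- make_residuals(m2, group = rep("g", 10))
  expect_equal(correlation_network(res1, "g")$r,
               correlation_network(res2, "g")$r, tolerance = 1e-12)
})

test_that("density thresholding obeys the floor edge-count rule", {
  set.seed(2)
  r <- cor(matrix(rnorm(50 * 90), 50, 90))
  bn <- threshold_by_density(r, 0.10)
  expect_equal(bn$n_edges, 400L) # floor(0.10 * 90 * 89 / 2) = floor(400.5)
  expect_equal(sum(bn$adjacency) / 2, 400)
  expect_equal(unname(diag(bn$adjacency)), rep(0, 90))
  expect_true(isSymmetric(bn$adjacency))
  # achieved density within one edge of request
  expect_lt(abs(bn$density - 0.10), 1 / (90 * 89 / 2))
})

test_that("thresholding near density 1 yields the complete graph", {
  set.seed(3)
  r <- cor(matrix(rnorm(20 * 6), 20, 6))
  bn <- threshold_by_density(r, 1)
  expect_equal(bn$adjacency, matrix(1, 6, 6) - diag(6),
               ignore_attr = TRUE)
  expect_error(threshold_by_density(r, 0.01), "zero edges")
  expect_error(threshold_by_density(r, 0), "in \\(0, 1\\]")
})

test_that("edge sets are nested across the density sweep", {
  set.seed(4)
  r <- cor(matrix(rnorm(30 * 40), 30, 40))
  sweep_ <- density_sweep(r, seq(0.10, 0.40, by = 0.05))
  for (k in seq_len(length(sweep_) - 1)) {
    a <- sweep_[[k]]$adjacency
    b <- sweep_[[k + 1]]$adjacency
    expect_true(all(b[a == 1] == 1))
  }
})

test_that("thresholding depends only on the rank order of entries", {
  set.seed(5)
  r <- cor(matrix(rnorm(25 * 15), 25, 15))
  r2 <- tanh(2 * r) # strictly monotone map, preserves order
  diag(r2) <- 1
  expect_equal(threshold_by_density(r, 0.2)$adjacency,
               threshold_by_density(r2, 0.2)$adjacency)
})

test_that("signed and absolute ranking differ when negatives are strong", {
  r <- diag(4)
  r[1, 2] <- r[2, 1] <- -0.9
  r[3, 4] <- r[4, 3] <- 0.5
  r[1, 3] <- r[3, 1] <- 0.1
  sg <- threshold_by_density(r, 2 / 6 + 1e-9, rank = "signed")
  ab <- threshold_by_density(r, 2 / 6 + 1e-9, rank = "absolute")
  expect_equal(sg$adjacency[1, 2], 0)
  expect_equal(ab$adjacency[1, 2], 1)
})

test_that("ties at the cutoff break lexicographically and reproducibly", {
  r <- matrix(0.5, 4, 4)
  diag(r) <- 1
  bn1 <- threshold_by_density(r, 0.34) # floor(0.34 * 6) = 2 of 6 tied edges
  bn2 <- threshold_by_density(r, 0.34)
  expect_identical(bn1$adjacency, bn2$adjacency)
  expect_equal(bn1$adjacency[1, 2], 1) # (1,2) precedes (1,3) ...
  expect_equal(bn1$adjacency[1, 3], 1)
  expect_equal(sum(bn1$adjacency) / 2, 2)
})

test_that("connectedness bookkeeping matches a BFS oracle", {
  set.seed(6)
  for (rep in 1:5) {
    r <- cor(matrix(rnorm(50 * 30), 50, 30))
    sw <- density_sweep(r, seq(0.08, 0.30, by = 0.02))
    conn <- check_connectedness(sw)
    oracle_min <- NA_real_
    for (k in seq_along(sw)) {
      lc <- oracle_largest_component(sw[[k]]$adjacency)
      expect_equal(conn$largest_component[k], lc)
      if (is.na(oracle_min) && lc == 30) oracle_min <- conn$density[k]
    }
    expect_equal(attr(conn, "min_connected_density"), oracle_min)
  }
})

test_that("hand-built disconnected graphs report the larger clique", {
  adj <- matrix(0, 7, 7)
  adj[1:4, 1:4] <- 1
  adj[5:7, 5:7] <- 1
  diag(adj) <- 0
  conn <- check_connectedness(structure(list(adjacency = adj,
                                             density = NA, group = NA),
                                        class = "binary_network"))
  expect_equal(conn$largest_component, 4L)
  expect_false(conn$connected)
})

test_that("network matrices round-trip through delimited text", {
  set.seed(7)
  m <- cor(matrix(rnorm(40), 10, 4))
  dimnames(m) <- list(paste0("R", 1:4), paste0("R", 1:4))
  p <- withr::local_tempfile(fileext = ".csv")
  write_network(m, p)
  back <- read_network_matrix(p)
  expect_equal(back, m, tolerance = 1e-12)
})
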