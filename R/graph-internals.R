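# Low-level graph primitives on dense 0/1 adjacency matrices.
# All functions assume a simple undirected graph: symmetric matrix, zero
# diagonal. Dense matrix algebra is deliberate -- the networks here are
# small (<= a few hundred nodes) and BLAS-backed products beat adjacency
# lists in R at this size, which matters inside permutation loops.

# All-pairs unweighted shortest-path distances by frontier expansion
# (matrix-product BFS from every source at once). Inf marks unreachable.
mn_dist_matrix <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  reach <- diag(n) > 0
  frontier <- diag(n)
  d <- 0L
  repeat {
    d <- d + 1L
    newly <- ((frontier %*% adj) > 0) & !reach
    if (!any(newly)) break
    D[newly] <- d
    reach <- reach | newly
    frontier <- newly + 0
  }
  D
}

# Per-node clustering coefficient: triangles through i over k_i(k_i-1)/2
# potential neighbour pairs; nodes of degree < 2 score 0.
mn_clustering_local <- function(adj) {
  k <- rowSums(adj)
  tri2 <- rowSums((adj %*% adj) * adj) # = diag(A^3) = 2 * triangles through i
  ci <- numeric(length(k))
  ok <- k >= 2
  ci[ok] <- tri2[ok] / (k[ok] * (k[ok] - 1))
  ci
}

# Characteristic path length: mean shortest-path distance over unordered
# node pairs. Disconnected graphs return NA unless require_connected, in
# which case they raise.
mn_lp <- function(adj, require_connected = TRUE) {
  D <- mn_dist_matrix(adj)
  d <- D[upper.tri(D)]
  if (any(!is.finite(d))) {
    if (require_connected) {
      stop("graph is disconnected; characteristic path length is undefined",
           call. = FALSE)
    }
    return(NA_real_)
  }
  mean(d)
}

# Brandes accumulation for unweighted betweenness. Counts each unordered
# source-target pair once (ordered-pair totals halved), matching the
# convention pinned by the star-graph value B(centre) = C(4,2) = 6.
mn_betweenness_raw <- function(adj) {
  n <- nrow(adj)
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ] != 0))
  B <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      dv1 <- dist[v] + 1L
      for (w in nbrs[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (idx in rev(seq_len(tail))) {
      w <- queue[idx]
      coeff <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coeff
      if (w != s) B[w] <- B[w] + delta[w]
    }
  }
  B / 2
}

# Vertices reachable from `start` (logical vector).
mn_reachable <- function(adj, start) {
  n <- nrow(adj)
  r <- logical(n)
  r[start] <- TRUE
  frontier <- r
  while (any(frontier)) {
    nxt <- as.vector((frontier + 0) %*% adj) > 0
    frontier <- nxt & !r
    r <- r | frontier
  }
  r
}

mn_component_sizes <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  sizes <- integer(0)
  while (!all(seen)) {
    s <- which(!seen)[1]
    comp <- mn_reachable(adj, s)
    sizes <- c(sizes, sum(comp))
    seen <- seen | comp
  }
  sort(sizes, decreasing = TRUE)
}

mn_is_connected <- function(adj) {
  nrow(adj) <= 1L || all(mn_reachable(adj, 1L))
}

# Upper-triangle index pairs in lexicographic (i, j) order; the tie-break
# order used everywhere edges are ranked.
mn_pair_index <- function(n) {
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) seq.int(a + 1L, n)),
              use.names = FALSE)
  list(i = i, j = j)
}

# Ranking of off-diagonal entries for density thresholding: strongest
# first under the chosen rule, ties broken by (i, j) lexicographic order
# for cross-platform determinism.
mn_edge_order <- function(r, rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  px <- mn_pair_index(nrow(r))
  vals <- r[cbind(px$i, px$j)]
  key <- if (rank == "signed") -vals else -abs(vals)
  ord <- order(key, px$i, px$j)
  list(i = px$i[ord], j = px$j[ord], vals = vals[ord])
}

# Adjacency keeping the first n_edges pairs of a ranking.
mn_adj_from_order <- function(ord, n_edges, n) {
  adj <- matrix(0, n, n)
  if (n_edges > 0) {
    sel <- seq_len(n_edges)
    idx <- cbind(ord$i[sel], ord$j[sel])
    adj[idx] <- 1
    adj[idx[, c(2, 1), drop = FALSE]] <- 1
  }
  adj
}

# Ring distance between node indices on a cycle of n nodes.
mn_ring_dist <- function(n) {
  idx <- seq_len(n)
  d <- abs(outer(idx, idx, "-"))
  pmin(d, n - d)
}

# Ring lattice: each node joined to its k_side nearest neighbours per side.
mn_ring_lattice <- function(n, k_side) {
  rd <- mn_ring_dist(n)
  adj <- (rd >= 1 & rd <= k_side) + 0
  adj
}

# Watts-Strogatz rewiring of a ring lattice: each lattice edge is, with
# probability p, re-attached at one endpoint to a uniformly chosen new
# node (no self-loops or multi-edges). Draws from R's RNG stream.
mn_watts_strogatz <- function(n, k_side, p) {
  adj <- mn_ring_lattice(n, k_side)
  px <- mn_pair_index(n)
  on_edge <- adj[cbind(px$i, px$j)] == 1
  ei <- px$i[on_edge]
  ej <- px$j[on_edge]
  for (e in seq_along(ei)) {
    if (stats::runif(1) < p) {
      i <- ei[e]
      j <- ej[e]
      cand <- which(adj[i, ] == 0)
      cand <- cand[cand != i]
      if (length(cand) == 0) next
      newj <- cand[sample.int(length(cand), 1)]
      adj[i, j] <- adj[j, i] <- 0
      adj[i, newj] <- adj[newj, i] <- 1
    }
  }
  adj
}
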