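# Brute-force graph oracles, written independently of the package's
# implementations (edge-list loops and Floyd-Warshall instead of matrix
# BFS and Brandes accumulation).

# Clustering by literal neighbour-pair counting.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) next
    e <- 0
    for (a in seq_len(k - 1)) {
      for (b in (a + 1):k) e <- e + adj[nb[a], nb[b]]
    }
    ci[i] <- e / (k * (k - 1) / 2)
  }
  list(cp = mean(ci), c_i = ci)
}

# All-pairs distances by Floyd-Warshall.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  D[adj == 1] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_lp <- function(adj) {
  D <- oracle_distances(adj)
  mean(D[upper.tri(D)])
}

# Betweenness by the combinatorial path-count identity: shortest-path
# counts sigma[s, t] from a DP over distance levels, then
# B(i) = sum_{s<t, i != s,t} sigma[s,i] * sigma[i,t] / sigma[s,t]
# restricted to pairs with d(s,i) + d(i,t) = d(s,t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  D <- oracle_distances(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  dmax <- max(D[is.finite(D)])
  for (d in seq_len(dmax)) {
    for (s in seq_len(n)) {
      for (t in which(D[s, ] == d)) {
        pred <- which(adj[, t] == 1 & D[s, ] == d - 1)
        sigma[s, t] <- sum(sigma[s, pred])
      }
    }
  }
  B <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (!is.finite(D[s, t])) next
      for (i in seq_len(n)) {
        if (i == s || i == t) next
        if (D[s, i] + D[i, t] == D[s, t]) {
          B[i] <- B[i] + sigma[s, i] * sigma[i, t] / sigma[s, t]
        }
      }
    }
  }
  B
}

# Connectivity by recursive DFS on an explicit stack.
oracle_connected <- function(adj) {
  n <- nrow(adj)
  if (n <= 1) return(TRUE)
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in which(adj[v, ] == 1)) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

oracle_largest_component <- function(adj) {
  n <- nrow(adj)
  seen <- logical(n)
  best <- 0L
  for (s in seq_len(n)) {
    if (seen[s]) next
    comp <- logical(n)
    stack <- s
    comp[s] <- TRUE
    while (length(stack)) {
      v <- stack[length(stack)]
      stack <- stack[-length(stack)]
      for (w in which(adj[v, ] == 1)) {
        if (!comp[w]) {
          comp[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    best <- max(best, sum(comp))
    seen <- seen | comp
  }
  best
}

# Adjacency from an edge bitmask over the upper triangle (lexicographic
# pair order), for exhaustive enumeration of labelled graphs.
adj_from_bitmask <- function(n, mask) {
  adj <- matrix(0, n, n)
  e <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (bitwAnd(mask, bitwShiftL(1L, e)) != 0) adj[i, j] <- adj[j, i] <- 1
      e <- e + 1L
    }
  }
  adj
}

# Random connected graph by rejection sampling on G(n, p).
random_connected_graph <- function(n, p = 0.3) {
  repeat {
    adj <- matrix(0, n, n)
    ut <- upper.tri(adj)
    adj[ut] <- as.numeric(stats::runif(sum(ut)) < p)
    adj <- adj + t(adj)
    if (oracle_connected(adj)) return(adj)
  }
}

# Small named fixtures.
graph_k4 <- function() matrix(1, 4, 4) - diag(4)
graph_path <- function(n) {
  adj <- matrix(0, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- 1
  adj
}
graph_cycle <- function(n) {
  adj <- graph_path(n)
  adj[1, n] <- adj[n, 1] <- 1
  adj
}
graph_star <- function(leaves) {
  adj <- matrix(0, leaves + 1, leaves + 1)
  adj[1, 2:(leaves + 1)] <- adj[2:(leaves + 1), 1] <- 1
  adj
}
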