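# The four network statistics: clustering coefficient, characteristic
# path length, small-world indices against degree-preserving null
# ensembles, and normalized betweenness centrality with hub calls.

#' Clustering coefficient
#'
#' Per-node clustering `C_i` — the fraction of a node's neighbour pairs
#' that are themselves connected (0 for degree < 2) — and the network
#' clustering coefficient `Cp`, the unweighted mean of `C_i` over all
#' nodes.
#'
#' @param net A `binary_network` or 0/1 adjacency matrix.
#' @return A list with `cp` (scalar) and `c_i` (named per-node vector).
#' @export
#' @examples
#' k4 <- matrix(1, 4, 4) - diag(4)
#' clustering_coefficient(k4)$cp # complete graph: 1
clustering_coefficient <- function(net) {
  adj <- mn_adj_matrix(net)
  ci <- mn_clustering_local(adj)
  names(ci) <- rownames(adj)
  list(cp = mean(ci), c_i = ci)
}

#' Characteristic path length
#'
#' Mean unweighted shortest-path distance over all unordered node pairs.
#' Defined only on connected graphs: strict mode (default) raises on a
#' disconnected input, permissive mode returns `NA`.
#'
#' @inheritParams clustering_coefficient
#' @param strict Error on disconnected input (default `TRUE`); otherwise
#'   return `NA`.
#' @return The scalar Lp (1 on a complete graph).
#' @export
characteristic_path_length <- function(net, strict = TRUE) {
  mn_lp(mn_adj_matrix(net), require_connected = strict)
}

#' Betweenness centrality
#'
#' Raw betweenness `B(i)` — the sum over unordered node pairs (s, t),
#' both different from i, of the fraction of shortest s-t paths passing
#' through i — and the normalized centrality `b_i = B(i) / mean(B)`. When
#' every `B(i)` is zero (e.g. a complete graph) all `b_i` are defined as
#' 0, with a warning.
#'
#' @inheritParams clustering_coefficient
#' @return A tibble: `region`, `betweenness`, `b` (normalized).
#' @export
#' @examples
#' star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 1
#' betweenness_centrality(star) # centre: B = 6, b = 5
betweenness_centrality <- function(net) {
  adj <- mn_adj_matrix(net)
  B <- mn_betweenness_raw(adj)
  if (mean(B) > 0) {
    b <- B / mean(B)
  } else {
    warning("all betweenness values are zero; normalized b_i set to 0",
            call. = FALSE)
    b <- rep(0, length(B))
  }
  tibble::tibble(
    region = rownames(adj) %||% paste0("R", seq_along(B)),
    betweenness = B,
    b = b)
}

#' Degree-preserving random reference ensemble
#'
#' Generates rewired null networks for the small-world normalization:
#' each reference is produced by Maslov-Sneppen double-edge-swap
#' rewiring (`n_swaps * E` attempted swaps), which preserves every node's
#' degree exactly. References are required to be connected; a
#' disconnected rewiring is retried up to `max_retries` times.
#'
#' @inheritParams clustering_coefficient
#' @param n_random Ensemble size (default 100).
#' @param n_swaps Attempted swaps per edge (default 10).
#' @param seed Optional seed for the rewiring stream.
#' @param max_retries Retries per reference when a rewiring comes out
#'   disconnected (default 100).
#' @return A list of 0/1 adjacency matrices.
#' @export
random_reference <- function(net, n_random = 100L, n_swaps = 10L,
                             seed = NULL, max_retries = 100L) {
  adj <- mn_adj_matrix(net)
  if (!is.null(seed)) set.seed(seed)
  e <- sum(adj) / 2
  if (e < 2) stop("graph needs at least 2 edges to rewire", call. = FALSE)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  lapply(seq_len(n_random), function(k) {
    for (try in seq_len(max_retries)) {
      gr <- igraph::rewire(g, igraph::keeping_degseq(niter = n_swaps * e))
      if (igraph::is_connected(gr)) {
        m <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
        dimnames(m) <- dimnames(adj)
        return(m)
      }
    }
    stop(sprintf(
      "no connected degree-preserving rewiring found in %d tries (density %.3f)",
      max_retries, e / (nrow(adj) * (nrow(adj) - 1) / 2)), call. = FALSE)
  })
}

#' Small-world indices
#'
#' Normalizes the clustering coefficient and characteristic path length
#' by their means over a degree-matched random reference ensemble:
#' `gamma = Cp / Cp_rand`, `lambda = Lp / Lp_rand`, and the small-world
#' index `sigma = gamma / lambda`. A network with `gamma >> 1`,
#' `lambda ~ 1`, hence `sigma > 1`, is called small-world.
#'
#' @inheritParams random_reference
#' @param ensemble Optional pre-built reference list (from
#'   [random_reference()]); built on the fly otherwise.
#' @return A one-row tibble: `cp`, `lp`, `cp_rand`, `lp_rand`, `gamma`,
#'   `lambda`, `sigma`, `n_random`.
#' @export
small_world <- function(net, n_random = 100L, n_swaps = 10L, seed = NULL,
                        ensemble = NULL) {
  adj <- mn_adj_matrix(net)
  if (is.null(ensemble)) {
    ensemble <- random_reference(net, n_random = n_random,
                                 n_swaps = n_swaps, seed = seed)
  }
  cp <- mean(mn_clustering_local(adj))
  lp <- mn_lp(adj)
  cp_rand <- mean(vapply(ensemble,
                         function(a) mean(mn_clustering_local(a)),
                         numeric(1)))
  lp_rand <- mean(vapply(ensemble, mn_lp, numeric(1)))
  if (cp_rand <= 0) {
    stop("reference ensemble has zero clustering; use a higher density",
         call. = FALSE)
  }
  gamma <- cp / cp_rand
  lambda <- lp / lp_rand
  tibble::tibble(cp = cp, lp = lp, cp_rand = cp_rand, lp_rand = lp_rand,
                 gamma = gamma, lambda = lambda, sigma = gamma / lambda,
                 n_random = length(ensemble))
}

#' Hub classification by normalized betweenness
#'
#' Flags as hubs the regions whose normalized betweenness centrality
#' exceeds a threshold: 1.5 by default, with 2.0 the common stricter
#' alternative.
#'
#' @inheritParams clustering_coefficient
#' @param threshold Hub cutoff on `b_i` (default 1.5).
#' @param group Optional group label carried into the table.
#' @return A tibble in region order: `region`, `b`, `hub`, `group`, with
#'   attribute `threshold`.
#' @export
classify_hubs <- function(net, threshold = 1.5, group = NULL) {
  bc <- betweenness_centrality(net)
  if (is.null(group)) {
    group <- if (inherits(net, "binary_network")) net$group else NA_character_
  }
  out <- tibble::tibble(region = bc$region, b = bc$b,
                        hub = bc$b > threshold, group = group)
  structure(out, threshold = threshold, class = class(out))
}

#' Hubs shared between two groups
#'
#' @param ... Two or more hub tables from [classify_hubs()].
#' @return A tibble of the regions flagged as hubs in every table, with
#'   each table's `b` value side by side.
#' @export
shared_hubs <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 2)
  shared <- Reduce(intersect, lapply(tabs, function(t) t$region[t$hub]))
  out <- tibble::tibble(region = shared)
  for (k in seq_along(tabs)) {
    t <- tabs[[k]]
    g <- t$group[1]
    col <- if (is.null(g) || is.na(g)) paste0("b_", k) else paste0("b_", g)
    out[[col]] <- t$b[match(shared, t$region)]
  }
  out
}

#' Graph-metric curves across the density sweep
#'
#' Runs the full per-group chain — correlation network, density
#' thresholding, graph statistics — and returns a long table of metric
#' values against density, the shape of the study's metric-vs-density
#' figures. Small-world indices (`gamma`, `lambda`, `sigma`) are included
#' when `n_random > 0`.
#'
#' @param residuals A `metab_residuals` tibble.
#' @param densities Density grid (default 0.10-0.40, step 0.01).
#' @param rank Edge ranking rule (see [threshold_by_density()]).
#' @param n_random Reference-ensemble size for small-world indices; 0
#'   skips them (default 0).
#' @param n_swaps Attempted swaps per edge during rewiring.
#' @param seed Optional seed for the rewiring stream.
#' @param strict Error on disconnected graphs (default); otherwise drop
#'   those densities with a warning.
#' @return A tibble of class `metab_curves`: `group`, `density`,
#'   `metric` (`cp`, `lp`, and optionally `gamma`, `lambda`, `sigma`),
#'   `value`.
#' @export
metric_curves <- function(residuals,
                          densities = seq(0.10, 0.40, by = 0.01),
                          rank = "signed", n_random = 0L, n_swaps = 10L,
                          seed = NULL, strict = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  groups <- sort(unique(residuals$group))
  rows <- purrr::map_dfr(groups, function(g) {
    net <- correlation_network(residuals, g)
    sweep <- density_sweep(net, densities, rank)
    purrr::map_dfr(sweep, function(bn) {
      adj <- bn$adjacency
      connected <- mn_is_connected(adj)
      if (!connected) {
        if (strict) {
          stop(sprintf(
            "group '%s' network disconnected at density %.2f (strict mode)",
            g, bn$density_requested), call. = FALSE)
        }
        warning(sprintf("dropping disconnected density %.2f for group '%s'",
                        bn$density_requested, g), call. = FALSE)
        return(tibble::tibble())
      }
      base <- tibble::tibble(
        group = g, density = bn$density_requested,
        metric = c("cp", "lp"),
        value = c(mean(mn_clustering_local(adj)), mn_lp(adj)))
      if (n_random > 0) {
        sw <- small_world(bn, n_random = n_random, n_swaps = n_swaps)
        base <- dplyr::bind_rows(base, tibble::tibble(
          group = g, density = bn$density_requested,
          metric = c("gamma", "lambda", "sigma"),
          value = c(sw$gamma, sw$lambda, sw$sigma)))
      }
      base
    })
  })
  structure(rows, class = c("metab_curves", class(rows)))
}
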