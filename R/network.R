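# Group correlation networks and density thresholding.

#' Inter-regional correlation network for one group
#'
#' Pearson correlation of every region pair's residuals across the
#' subjects of one group — the metabolic-covariance network for that
#' group.
#'
#' @param residuals A `metab_residuals` tibble (see [residualize()]).
#' @param group Which group to use (`"patient"` or `"control"`).
#' @return An object of class `corr_network`: a list with `r` (regions x
#'   regions correlation matrix), `group`, and `n_subjects`.
#' @export
correlation_network <- function(residuals, group) {
  if (!group %in% residuals$group) {
    stop("group '", group, "' not present in residuals", call. = FALSE)
  }
  m <- mn_value_matrix(residuals[residuals$group == group, ])
  if (nrow(m) < 3L) {
    stop("group '", group, "' has fewer than 3 subjects", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance region(s) in group '", group, "': ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- stats::cor(m)
  structure(list(r = r, group = group, n_subjects = nrow(m)),
            class = "corr_network")
}

#' @export
print.corr_network <- function(x, ...) {
  cat(sprintf("<corr_network> group '%s': %d regions, %d subjects\n",
              x$group, nrow(x$r), x$n_subjects))
  invisible(x)
}

mn_cor_matrix <- function(net) {
  if (inherits(net, "corr_network")) return(net$r)
  if (inherits(net, "binary_network")) {
    stop("expected a correlation network, got a binary network",
         call. = FALSE)
  }
  stopifnot(is.matrix(net), nrow(net) == ncol(net))
  net
}

mn_adj_matrix <- function(net) {
  if (inherits(net, "binary_network")) return(net$adjacency)
  stopifnot(is.matrix(net), nrow(net) == ncol(net))
  net
}

#' Binarize a correlation network at a target density
#'
#' Keeps the `E = floor(D * N(N-1)/2)` strongest edges and drops the
#' rest. "Strongest" defaults to the signed correlation (most positive
#' first); `rank = "absolute"` ranks by magnitude instead. Ties at the
#' cutoff are broken by lexicographic region-pair order, so the result is
#' identical across platforms, and edge sets are nested across densities
#' by construction.
#'
#' @param net A `corr_network` or a symmetric numeric matrix.
#' @param density Target edge density in (0, 1]; 1 keeps every pair
#'   (complete graph).
#' @param rank Edge ranking rule: `"signed"` (default) or `"absolute"`.
#' @return An object of class `binary_network`: `adjacency` (0/1
#'   symmetric, zero diagonal), achieved `density`, requested
#'   `density_requested`, `n_edges`, `rank`, and `group` (if known).
#' @export
threshold_by_density <- function(net, density, rank = c("signed",
                                                        "absolute")) {
  rank <- match.arg(rank)
  r <- mn_cor_matrix(net)
  if (!is.numeric(density) || length(density) != 1L ||
      density <= 0 || density > 1) {
    stop("`density` must be a scalar in (0, 1]", call. = FALSE)
  }
  n <- nrow(r)
  e_max <- n * (n - 1) / 2
  n_edges <- floor(density * e_max)
  if (n_edges < 1) {
    stop(sprintf("density %.3f yields zero edges at %d regions",
                 density, n), call. = FALSE)
  }
  ord <- mn_edge_order(r, rank)
  adj <- mn_adj_from_order(ord, n_edges, n)
  dimnames(adj) <- dimnames(r)
  structure(
    list(adjacency = adj,
         density = n_edges / e_max,
         density_requested = density,
         n_edges = as.integer(n_edges),
         rank = rank,
         group = if (inherits(net, "corr_network")) net$group else NA_character_),
    class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d regions, %d edges (density %.3f)%s\n",
              nrow(x$adjacency), x$n_edges, x$density,
              if (is.na(x$group)) "" else paste0(", group '", x$group, "'")))
  invisible(x)
}

#' Threshold a correlation network across a density sweep
#'
#' Applies [threshold_by_density()] over an increasing density grid
#' (default 10\% to 40\% in 1\% steps). Because all densities share one
#' edge ranking, edge sets are nested: every edge present at a lower
#' density is present at all higher densities.
#'
#' @inheritParams threshold_by_density
#' @param densities Strictly increasing densities in (0, 1).
#' @return A `density_sweep`: a list of `binary_network` objects, one per
#'   density, with attributes `densities`, `group`, `rank`.
#' @export
density_sweep <- function(net, densities = seq(0.10, 0.40, by = 0.01),
                          rank = c("signed", "absolute")) {
  rank <- match.arg(rank)
  if (any(diff(densities) <= 0)) {
    stop("`densities` must be strictly increasing", call. = FALSE)
  }
  nets <- lapply(densities, function(d) threshold_by_density(net, d, rank))
  structure(nets,
            densities = densities,
            group = if (inherits(net, "corr_network")) net$group else NA_character_,
            rank = rank,
            class = "density_sweep")
}

#' Largest-component bookkeeping for a density sweep
#'
#' Path-based statistics (Lp, betweenness) are only defined on connected
#' graphs. This reports the largest connected-component size at each
#' density and the minimum density at which the network is fully
#' connected; in strict mode downstream metric computation refuses
#' disconnected graphs, in permissive mode those densities are dropped
#' with a warning.
#'
#' @param sweep A `density_sweep`, or a single `binary_network`.
#' @return A tibble `density`, `n_edges`, `largest_component`,
#'   `connected`, with attribute `min_connected_density` (NA if never
#'   fully connected).
#' @export
check_connectedness <- function(sweep) {
  if (inherits(sweep, "binary_network")) sweep <- list(sweep)
  rows <- purrr::map_dfr(sweep, function(bn) {
    adj <- mn_adj_matrix(bn)
    lc <- mn_component_sizes(adj)[1]
    tibble::tibble(
      density = if (inherits(bn, "binary_network")) bn$density else
        sum(adj) / (nrow(adj) * (nrow(adj) - 1)),
      n_edges = as.integer(sum(adj) / 2),
      largest_component = as.integer(lc),
      connected = lc == nrow(adj))
  })
  structure(rows,
            min_connected_density =
              if (any(rows$connected)) min(rows$density[rows$connected])
              else NA_real_,
            class = class(rows))
}

#' Write / read a square network matrix as delimited text
#'
#' Serializes a correlation or adjacency matrix with a region-name header
#' row and leading region-name column, comma-separated UTF-8.
#'
#' @param net A `corr_network`, `binary_network`, or square matrix.
#' @param path File path.
#' @return `write_network()` the input, invisibly; `read_network_matrix()`
#'   a named square matrix.
#' @export
write_network <- function(net, path) {
  m <- if (inherits(net, "binary_network")) net$adjacency else
    mn_cor_matrix(net)
  df <- dplyr::bind_cols(tibble::tibble(region = rownames(m) %||%
                                          paste0("R", seq_len(nrow(m)))),
                         tibble::as_tibble(m, .name_repair = "minimal"))
  readr::write_csv(df, path)
  invisible(net)
}

#' @rdname write_network
#' @export
read_network_matrix <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  m
}
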