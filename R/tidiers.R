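# broom-style accessors for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a correlation network into an edge list
#'
#' @param x A `corr_network`.
#' @param ... Unused.
#' @return A tibble `region_a`, `region_b`, `r` for every unordered pair.
#' @export
tidy.corr_network <- function(x, ...) {
  px <- mn_pair_index(nrow(x$r))
  nm <- rownames(x$r) %||% paste0("R", seq_len(nrow(x$r)))
  tibble::tibble(region_a = nm[px$i], region_b = nm[px$j],
                 r = x$r[cbind(px$i, px$j)])
}

#' @export
glance.corr_network <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  tibble::tibble(group = x$group, n_subjects = x$n_subjects,
                 n_regions = nrow(x$r), mean_r = mean(off),
                 sd_r = stats::sd(off))
}

#' Tidy a binary network into its edge list
#'
#' @param x A `binary_network`.
#' @param ... Unused.
#' @return A tibble `region_a`, `region_b` for every edge present.
#' @export
tidy.binary_network <- function(x, ...) {
  adj <- x$adjacency
  px <- mn_pair_index(nrow(adj))
  keep <- adj[cbind(px$i, px$j)] == 1
  nm <- rownames(adj) %||% paste0("R", seq_len(nrow(adj)))
  tibble::tibble(region_a = nm[px$i][keep], region_b = nm[px$j][keep])
}

#' @export
glance.binary_network <- function(x, ...) {
  tibble::tibble(group = x$group, n_regions = nrow(x$adjacency),
                 n_edges = x$n_edges, density = x$density,
                 connected = mn_is_connected(x$adjacency))
}

#' Summarize a density sweep
#'
#' @param x A `density_sweep`.
#' @param ... Unused.
#' @return One row per density: `density`, `n_edges`,
#'   `largest_component`, `connected`.
#' @export
tidy.density_sweep <- function(x, ...) {
  tibble::as_tibble(check_connectedness(x))
}

#' @export
tidy.metab_permutation <- function(x, ...) {
  tibble::as_tibble(as.data.frame(x))
}

#' @export
glance.metab_permutation <- function(x, ...) {
  tibble::tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant),
    reps = attr(x, "reps"),
    resampled = attr(x, "resampled"),
    alternative = attr(x, "alternative"))
}
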