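# Label-permutation inference for between-group differences in network
# statistics across the density sweep.

#' Shuffle group labels preserving group sizes
#'
#' @param group A vector of group labels (two groups).
#' @param seed Optional seed.
#' @return The labels uniformly permuted (group sizes unchanged).
#' @export
permute_groups <- function(group, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  group[sample.int(length(group))]
}

# Metric values for one group's subjects x regions residual matrix over
# the density grid. Returns metrics x densities for scalar metrics; the
# per-node metric "bi" yields regions x densities. Raises a condition of
# class "mn_disconnected" when a path metric meets a disconnected graph.
mn_group_stat <- function(m, densities, metrics, rank, n_random, n_swaps) {
  r <- suppressWarnings(stats::cor(m))
  if (anyNA(r)) {
    stop("zero-variance region in a group; correlations undefined",
         call. = FALSE)
  }
  n <- nrow(r)
  ord <- mn_edge_order(r, rank)
  e_max <- n * (n - 1) / 2
  per_node <- identical(metrics, "bi")
  need_paths <- any(metrics %in% c("lp", "lambda", "sigma", "bi"))
  need_sw <- any(metrics %in% c("gamma", "lambda", "sigma"))
  out <- if (per_node) {
    matrix(NA_real_, n, length(densities),
           dimnames = list(colnames(m), NULL))
  } else {
    matrix(NA_real_, length(metrics), length(densities),
           dimnames = list(metrics, NULL))
  }
  for (di in seq_along(densities)) {
    adj <- mn_adj_from_order(ord, floor(densities[di] * e_max), n)
    if (need_paths) {
      D <- mn_dist_matrix(adj)
      if (any(!is.finite(D[upper.tri(D)]))) {
        cond <- structure(
          class = c("mn_disconnected", "error", "condition"),
          list(message = sprintf("disconnected graph at density %.3f",
                                 densities[di]),
               call = NULL))
        stop(cond)
      }
      lp <- mean(D[upper.tri(D)])
    }
    if (per_node) {
      B <- mn_betweenness_raw(adj)
      out[, di] <- if (mean(B) > 0) B / mean(B) else 0
      next
    }
    cp <- mean(mn_clustering_local(adj))
    if (need_sw) {
      ens <- random_reference(adj, n_random = n_random, n_swaps = n_swaps)
      cp_rand <- mean(vapply(ens, function(a) mean(mn_clustering_local(a)),
                             numeric(1)))
      lp_rand <- mean(vapply(ens, mn_lp, numeric(1)))
      gamma <- cp / cp_rand
      lambda <- lp / lp_rand
    }
    for (mt in metrics) {
      out[mt, di] <- switch(mt,
        cp = cp, lp = lp, gamma = gamma, lambda = lambda,
        sigma = gamma / lambda,
        stop("unknown metric: ", mt, call. = FALSE))
    }
  }
  out
}

# Patient-minus-control metric difference for a given label assignment.
mn_split_diff <- function(Y, labels, groups, densities, metrics, rank,
                          n_random, n_swaps) {
  pat <- mn_group_stat(Y[labels == groups[1], , drop = FALSE],
                       densities, metrics, rank, n_random, n_swaps)
  con <- mn_group_stat(Y[labels == groups[2], , drop = FALSE],
                       densities, metrics, rank, n_random, n_swaps)
  pat - con
}

#' Permutation test for group differences in network statistics
#'
#' For each density, the observed patient-minus-control difference in a
#' network statistic is compared against a null distribution built by
#' shuffling the subject group labels `reps` times; each permutation
#' re-runs the entire chain — group correlation matrices, density
#' thresholding, metric computation — so the null reflects network
#' re-construction, not just metric noise. One relabelling is shared
#' across all densities and metrics, so density-wise results have the
#' correct joint null.
#'
#' The one-tailed decision rule (default `alternative = "greater"`) calls
#' a difference significant when it exceeds the 95th percentile of its
#' null; the empirical p value uses the add-one rule
#' `p = (#\{null >= observed\} + 1) / (reps + 1)`, which can never be
#' exactly zero. Permutations on which a path-based statistic meets a
#' disconnected graph are resampled (and counted); more than
#' `max_resample_frac * reps` resamples aborts.
#'
#' Scalar statistics (`cp`, `lp`, `gamma`, `lambda`, `sigma`) may be
#' tested jointly; the per-node statistic `"bi"` (normalized betweenness)
#' must be requested alone and yields region-wise results. Small-world
#' statistics rebuild a reduced random-reference ensemble (`n_random`,
#' default 20) inside every permutation, which dominates their cost.
#'
#' @param residuals A `metab_residuals` tibble.
#' @param metrics Character vector of scalar metrics, or `"bi"`.
#' @param densities Density grid.
#' @param reps Number of label permutations (default 1000).
#' @param seed Optional seed governing the whole test.
#' @param rank Edge ranking rule.
#' @param alternative `"greater"` (patient > control, the default),
#'   `"less"`, or `"two.sided"`.
#' @param groups Length-2 character vector; the difference is
#'   `groups[1] - groups[2]` (default patient minus control).
#' @param n_random Reference-ensemble size inside permutations (only for
#'   small-world metrics; default 20).
#' @param n_swaps Attempted swaps per edge during rewiring.
#' @param max_resample_frac Abort threshold on the resampled fraction.
#' @return A tibble of class `metab_permutation` with columns `metric`
#'   (or `region` for `"bi"`), `density`, `observed`, `critical`, `p`,
#'   `significant`, and attributes `null` (the permuted differences),
#'   `reps`, `alternative`, `resampled`.
#' @export
permutation_test <- function(residuals, metrics = c("cp", "lp"),
                             densities = seq(0.10, 0.40, by = 0.01),
                             reps = 1000L, seed = NULL, rank = "signed",
                             alternative = c("greater", "less",
                                             "two.sided"),
                             groups = c("patient", "control"),
                             n_random = 20L, n_swaps = 10L,
                             max_resample_frac = 0.1) {
  alternative <- match.arg(alternative)
  if ("bi" %in% metrics && length(metrics) > 1) {
    stop("the per-node metric 'bi' must be tested alone", call. = FALSE)
  }
  if (!all(groups %in% residuals$group)) {
    stop("groups not present in residuals: ",
         paste(setdiff(groups, residuals$group), collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  Y <- mn_value_matrix(residuals)
  labels <- residuals$group

  observed <- mn_split_diff(Y, labels, groups, densities, metrics, rank,
                            n_random, n_swaps)
  null <- array(NA_real_, c(reps, nrow(observed), ncol(observed)),
                dimnames = list(NULL, rownames(observed), NULL))
  resampled <- 0L
  max_resample <- max_resample_frac * reps
  r <- 1L
  while (r <= reps) {
    perm <- labels[sample.int(length(labels))]
    d <- tryCatch(
      mn_split_diff(Y, perm, groups, densities, metrics, rank,
                    n_random, n_swaps),
      mn_disconnected = function(e) NULL)
    if (is.null(d)) {
      resampled <- resampled + 1L
      if (resampled > max_resample) {
        stop(sprintf(
          "more than %.0f%% of permutations hit disconnected graphs; %s",
          100 * max_resample_frac,
          "raise the density range or use fewer regions"), call. = FALSE)
      }
      next
    }
    null[r, , ] <- d
    r <- r + 1L
  }

  rows <- purrr::map_dfr(seq_len(nrow(observed)), function(mi) {
    purrr::map_dfr(seq_along(densities), function(di) {
      dec <- mn_perm_decision(observed[mi, di], null[, mi, di], alternative)
      tibble::tibble(metric = rownames(observed)[mi],
                     density = densities[di],
                     observed = unname(observed[mi, di]),
                     critical = unname(dec$critical), p = dec$p,
                     significant = unname(dec$significant))
    })
  })
  if (identical(metrics, "bi")) {
    names(rows)[names(rows) == "metric"] <- "region"
  }
  structure(rows,
            null = null, reps = reps, alternative = alternative,
            groups = groups, resampled = resampled, seed = seed,
            metrics = metrics, densities = densities,
            class = c("metab_permutation", class(rows)))
}

# Decision + add-one p for one observed value against its null.
mn_perm_decision <- function(obs, null, alternative) {
  switch(alternative,
    greater = list(
      critical = unname(stats::quantile(null, 0.95)),
      p = (sum(null >= obs) + 1) / (length(null) + 1),
      significant = obs > unname(stats::quantile(null, 0.95))),
    less = list(
      critical = unname(stats::quantile(null, 0.05)),
      p = (sum(null <= obs) + 1) / (length(null) + 1),
      significant = obs < unname(stats::quantile(null, 0.05))),
    two.sided = {
      lo <- unname(stats::quantile(null, 0.025))
      hi <- unname(stats::quantile(null, 0.975))
      list(critical = hi,
           p = (sum(abs(null) >= abs(obs)) + 1) / (length(null) + 1),
           significant = obs < lo | obs > hi)
    })
}

#' Two-tailed re-decision of a permutation test
#'
#' Re-evaluates an existing [permutation_test()] result against the
#' 2.5th/97.5th percentiles of the same stored null distributions,
#' without re-running any permutation. Useful for effects in the
#' unanticipated direction (e.g. decreased centrality).
#'
#' @param result A `metab_permutation` object.
#' @return A tibble like the input with `critical_low`, `critical_high`,
#'   two-sided `p`, and symmetric `significant`.
#' @export
two_tailed <- function(result) {
  stopifnot(inherits(result, "metab_permutation"))
  null <- attr(result, "null")
  densities <- attr(result, "densities")
  key <- names(result)[1] # metric or region
  out <- tibble::as_tibble(result[c(key, "density", "observed")])
  out$critical_low <- NA_real_
  out$critical_high <- NA_real_
  out$p <- NA_real_
  out$significant <- NA
  ids <- dimnames(null)[[2]]
  for (row in seq_len(nrow(out))) {
    mi <- match(out[[key]][row], ids)
    di <- match(out$density[row], densities)
    nd <- null[, mi, di]
    lo <- unname(stats::quantile(nd, 0.025))
    hi <- unname(stats::quantile(nd, 0.975))
    obs <- out$observed[row]
    out$critical_low[row] <- lo
    out$critical_high[row] <- hi
    out$p[row] <- (sum(abs(nd) >= abs(obs)) + 1) / (length(nd) + 1)
    out$significant[row] <- obs < lo | obs > hi
  }
  out
}
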