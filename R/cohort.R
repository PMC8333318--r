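#' Specify a synthetic two-group cohort
#'
#' Defines the generative conditions for a synthetic cohort of regional
#' glucose-metabolism values: two groups (`control`, `patient`) whose
#' inter-regional correlation structure is controlled through latent binary
#' graphs, with additive linear covariate effects (age, sex, fasting
#' glucose) and Gaussian residual noise.
#'
#' The control group's latent graph is a Watts-Strogatz small-world graph:
#' a ring lattice in which every node is joined to its `lattice_degree`
#' nearest neighbours (half per side), each lattice edge rewired to a
#' random endpoint with probability `rewire_prob`. The patient group's
#' latent graph is a perturbation of the control graph whose strength is
#' `patient_effect`:
#'
#' * `"rewired"` — a fraction `patient_effect` of the long-range shortcut
#'   edges is removed and replaced by triangle-closing local edges, raising
#'   both the clustering coefficient and the characteristic path length of
#'   the patient graph (edge count preserved).
#' * `"block"` — the same fraction of between-block edges (nodes cut into
#'   `n_blocks` contiguous modules) is moved to within-block pairs,
#'   increasing modularity.
#' * `"shared"` — both groups use the identical latent graph (null
#'   construction; any detected group difference is a false positive).
#'
#' The latent graph maps to a covariance as adjacency plus diagonal
#' loading sized so the smallest eigenvalue is 0.05, then standardized to
#' a correlation matrix; subjects are drawn from the corresponding
#' multivariate Gaussian.
#'
#' @param n_per_group Subjects per group (>= 3; default 50).
#' @param n_regions Number of regions (>= 4; default 90, labelled with AAL
#'   abbreviations).
#' @param covariance_model `"rewired"`, `"block"` or `"shared"` (see
#'   Details).
#' @param patient_effect Perturbation strength in `[0, 1]`: the fraction of
#'   eligible edges rewired toward the patient topology. 0 makes the groups
#'   exchangeable.
#' @param covariate_betas Named numeric vector of linear effects added to
#'   every region, in metabolic units per covariate unit; names must be
#'   `age`, `sex`, `glucose`.
#' @param noise_sd Residual standard deviation in metabolic units (> 0).
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @param lattice_degree Even node degree of the latent ring lattice;
#'   default 6, capped below `n_regions` for very small cohorts. Kept low
#'   so the positive-definite loading admits edge correlations strong
#'   enough to be recoverable from realistic sample sizes.
#' @param rewire_prob Watts-Strogatz rewiring probability (default 0.3).
#' @param n_blocks Modules for the `"block"` model (default 6).
#' @param baseline Mean metabolism level added to all values (default 10).
#'
#' @return An object of class `cohort_spec`.
#' @seealso [generate_cohort()], [latent_graph_metrics()]
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = 20, n_regions = 40, seed = 7)
#' cohort <- generate_cohort(spec)
cohort_spec <- function(n_per_group = 50L,
                        n_regions = 90L,
                        covariance_model = c("rewired", "block", "shared"),
                        patient_effect = 0.5,
                        covariate_betas = c(age = 0.02, sex = 0.1,
                                            glucose = 0.1),
                        noise_sd = 0.2,
                        seed = 1L,
                        lattice_degree = NULL,
                        rewire_prob = 0.3,
                        n_blocks = 6L,
                        baseline = 10) {
  covariance_model <- match.arg(covariance_model)
  n_per_group <- as.integer(n_per_group)
  n_regions <- as.integer(n_regions)
  if (is.na(n_per_group) || n_per_group < 3L) {
    stop("`n_per_group` must be an integer >= 3", call. = FALSE)
  }
  if (is.na(n_regions) || n_regions < 4L) {
    stop("`n_regions` must be an integer >= 4", call. = FALSE)
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd <= 0) {
    stop("`noise_sd` must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(patient_effect) || length(patient_effect) != 1L ||
      patient_effect < 0 || patient_effect > 1) {
    stop("`patient_effect` must be a scalar in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(covariate_betas) ||
      !setequal(names(covariate_betas), c("age", "sex", "glucose"))) {
    stop("`covariate_betas` must be a numeric vector named age, sex, glucose",
         call. = FALSE)
  }
  seed <- as.integer(seed)
  if (is.na(seed) || seed < 0L || seed > .Machine$integer.max - 10L) {
    stop("`seed` must be a non-negative 32-bit integer", call. = FALSE)
  }
  if (is.null(lattice_degree)) {
    lattice_degree <- min(6L, 2L * ((n_regions - 1L) %/% 2L))
  }
  lattice_degree <- as.integer(lattice_degree)
  if (lattice_degree < 2L || lattice_degree %% 2L != 0L ||
      lattice_degree >= n_regions) {
    stop("`lattice_degree` must be even, >= 2, and < n_regions",
         call. = FALSE)
  }
  structure(
    list(
      n_per_group = n_per_group,
      n_regions = n_regions,
      covariance_model = covariance_model,
      patient_effect = patient_effect,
      covariate_betas = covariate_betas[c("age", "sex", "glucose")],
      noise_sd = noise_sd,
      seed = seed,
      lattice_degree = lattice_degree,
      rewire_prob = rewire_prob,
      n_blocks = as.integer(n_blocks),
      baseline = baseline
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec>\n")
  cat(sprintf("  %d subjects/group x %d regions, model '%s'\n",
              x$n_per_group, x$n_regions, x$covariance_model))
  cat(sprintf("  patient_effect %.2f, noise_sd %.2f, seed %d\n",
              x$patient_effect, x$noise_sd, x$seed))
  invisible(x)
}

# Latent graph pair for a spec. Uses the spec seed directly so the graphs
# can be regenerated without drawing the cohort (subject-level sampling
# uses seed + 1; see generate_cohort).
mn_latent_graphs <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n_regions
  k_side <- spec$lattice_degree %/% 2L
  control <- mn_watts_strogatz(n, k_side, spec$rewire_prob)
  patient <- switch(
    spec$covariance_model,
    shared = control,
    rewired = mn_perturb_rewired(control, spec$patient_effect, n, k_side),
    block = mn_perturb_block(control, spec$patient_effect, spec$n_blocks)
  )
  list(control = control, patient = patient)
}

# Remove a fraction of long-range shortcuts (ring distance > k_side) and
# replace each with a triangle-closing local edge; skips removals that
# would disconnect the graph so path-based latent metrics stay defined.
mn_perturb_rewired <- function(adj, effect, n, k_side) {
  if (effect == 0) return(adj)
  rd <- mn_ring_dist(n)
  px <- mn_pair_index(n)
  is_edge <- adj[cbind(px$i, px$j)] == 1
  is_short <- rd[cbind(px$i, px$j)] > k_side
  sc <- which(is_edge & is_short)
  n_move <- round(effect * length(sc))
  if (n_move == 0) return(adj)
  sc <- sc[sample.int(length(sc))]
  moved <- 0L
  for (e in sc) {
    if (moved >= n_move) break
    i <- px$i[e]; j <- px$j[e]
    adj[i, j] <- adj[j, i] <- 0
    if (!mn_is_connected(adj)) {
      adj[i, j] <- adj[j, i] <- 1
      next
    }
    res <- mn_close_triangle(adj)
    if (!is.null(res)) {
      adj <- res
      moved <- moved + 1L
    } else {
      adj[i, j] <- adj[j, i] <- 1
    }
  }
  adj
}

# Add one edge between two unconnected neighbours of a random node.
# Returns the updated adjacency, or NULL if no such pair exists.
mn_close_triangle <- function(adj) {
  n <- nrow(adj)
  for (u in sample.int(n)) {
    nb <- which(adj[u, ] == 1)
    if (length(nb) < 2) next
    sub <- adj[nb, nb, drop = FALSE]
    open <- which(upper.tri(sub) & sub == 0, arr.ind = TRUE)
    if (nrow(open) == 0) next
    pick <- open[sample.int(nrow(open), 1L), ]
    v <- nb[pick[1]]; w <- nb[pick[2]]
    adj[v, w] <- adj[w, v] <- 1
    return(adj)
  }
  NULL
}

# Move a fraction of between-block edges to within-block non-edges.
mn_perturb_block <- function(adj, effect, n_blocks) {
  if (effect == 0) return(adj)
  n <- nrow(adj)
  block <- cut(seq_len(n), n_blocks, labels = FALSE)
  px <- mn_pair_index(n)
  same <- block[px$i] == block[px$j]
  is_edge <- adj[cbind(px$i, px$j)] == 1
  between <- which(is_edge & !same)
  within_open <- which(!is_edge & same)
  n_move <- min(round(effect * length(between)), length(within_open))
  if (n_move == 0) return(adj)
  between <- between[sample.int(length(between))]
  add <- within_open[sample.int(length(within_open), n_move)]
  moved <- 0L
  for (e in between) {
    if (moved >= n_move) break
    i <- px$i[e]; j <- px$j[e]
    adj[i, j] <- adj[j, i] <- 0
    if (!mn_is_connected(adj)) {
      adj[i, j] <- adj[j, i] <- 1
      next
    }
    moved <- moved + 1L
    a <- px$i[add[moved]]; b <- px$j[add[moved]]
    adj[a, b] <- adj[b, a] <- 1
  }
  adj
}

# Latent binary graph -> correlation matrix: adjacency plus diagonal
# loading sized so the smallest eigenvalue is 0.05, standardized to unit
# diagonal. Warns if loading was needed beyond the usual spectral bound
# (it always is for non-empty graphs; the warning fires only if the
# resulting matrix still fails a positive-definiteness check).
mn_graph_to_cor <- function(adj) {
  ev_min <- min(eigen(adj, symmetric = TRUE, only.values = TRUE)$values)
  d <- 0.05 - ev_min
  sigma <- adj + diag(d, nrow(adj))
  r <- stats::cov2cor(sigma)
  ev <- min(eigen(r, symmetric = TRUE, only.values = TRUE)$values)
  if (ev <= 0) {
    warning("latent covariance not positive definite after loading; ",
            "adding extra ridge", call. = FALSE)
    r <- stats::cov2cor(sigma + diag(abs(ev) + 0.05, nrow(adj)))
  }
  r
}

#' Generate a synthetic cohort of regional metabolism values
#'
#' Draws `2 * n_per_group` subjects. Control subjects come from a
#' multivariate Gaussian whose correlation matrix is derived from the
#' control latent graph; patient subjects from the perturbed patient
#' graph. Linear covariate effects and Gaussian noise are added, and the
#' whole table is shifted to be strictly positive. Covariate
#' distributions mirror a matched two-group design: sex balanced 0/1
#' within each group, age about 52-54 years (SD 8), fasting glucose about
#' 5.3-5.4 mmol/L.
#'
#' All randomness flows from `spec$seed`: the latent graphs consume the
#' stream seeded with `seed`, subject-level sampling the stream seeded
#' with `seed + 1`, so [latent_graph_metrics()] can regenerate the graphs
#' independently of the cohort draw.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble of class `metab_cohort` with columns `subject_id`,
#'   `group` (`"control"`/`"patient"`), `age`, `sex`, `glucose`, followed
#'   by one column per region. Attributes `region_names` and `spec` carry
#'   the node labels and generating conditions.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = 10, n_regions = 20,
#'                                       seed = 1))
#' dplyr::count(cohort, group)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  graphs <- mn_latent_graphs(spec)
  set.seed(spec$seed + 1L)
  n <- spec$n_per_group
  p <- spec$n_regions
  regions <- mn_region_names(p)

  chol_u <- lapply(graphs, function(a) chol(mn_graph_to_cor(a)))

  age <- c(round(mn_rnorm_clamped(n, 53.5, 8.0, 36, 76), 1),
           round(mn_rnorm_clamped(n, 52.1, 8.7, 36, 76), 1))
  sex <- rep(rep_len(c(0, 1), n), 2)
  glucose <- c(round(mn_rnorm_clamped(n, 5.30, 0.41, 3.5, 7.5), 2),
               round(mn_rnorm_clamped(n, 5.40, 0.67, 3.5, 7.5), 2))
  group <- rep(c("control", "patient"), each = n)

  z_con <- matrix(stats::rnorm(n * p), n, p) %*% chol_u$control
  z_pat <- matrix(stats::rnorm(n * p), n, p) %*% chol_u$patient
  signal <- rbind(z_con, z_pat)
  noise <- matrix(stats::rnorm(2 * n * p, sd = spec$noise_sd), 2 * n, p)

  betas <- spec$covariate_betas
  covar_shift <- age * betas[["age"]] + sex * betas[["sex"]] +
    glucose * betas[["glucose"]]
  values <- spec$baseline + signal + noise + covar_shift

  lo <- min(values)
  if (lo <= 0) values <- values + (0.1 - lo)
  colnames(values) <- regions

  out <- tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(2 * n)),
    group = group,
    age = age,
    sex = sex,
    glucose = glucose
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(values))
  structure(out,
            region_names = regions,
            spec = spec,
            latent_graphs = graphs,
            class = c("metab_cohort", class(out)))
}

mn_rnorm_clamped <- function(n, mean, sd, lo, hi) {
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)
}

#' Graph statistics of a cohort's latent networks
#'
#' Regenerates the latent control and patient graphs implied by a
#' [cohort_spec()] (without drawing subjects) and returns their clustering
#' coefficient and characteristic path length, to serve as ground-truth
#' recovery targets for the sampled networks.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `group`, `density`, `cp`, `lp`.
#' @export
latent_graph_metrics <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  graphs <- mn_latent_graphs(spec)
  purrr::map_dfr(c("control", "patient"), function(g) {
    adj <- graphs[[g]]
    n <- nrow(adj)
    tibble::tibble(
      group = g,
      density = sum(adj) / (n * (n - 1)),
      cp = mean(mn_clustering_local(adj)),
      lp = mn_lp(adj, require_connected = FALSE)
    )
  })
}

# ---- cohort accessors -------------------------------------------------

# Region columns of a cohort/residual tibble as a plain matrix.
mn_value_matrix <- function(x) {
  regions <- attr(x, "region_names")
  if (is.null(regions)) {
    regions <- setdiff(names(x),
                       c("subject_id", "group", "age", "sex", "glucose"))
  }
  m <- as.matrix(as.data.frame(x)[, regions, drop = FALSE])
  rownames(m) <- x$subject_id
  m
}

mn_check_cohort <- function(cohort) {
  need <- c("subject_id", "group")
  if (!all(need %in% names(cohort))) {
    stop("cohort must have columns subject_id and group", call. = FALSE)
  }
  if (anyNA(cohort)) stop("cohort contains missing values", call. = FALSE)
  groups <- unique(cohort$group)
  if (length(groups) != 2L) {
    stop("cohort must contain exactly two groups, found: ",
         paste(groups, collapse = ", "), call. = FALSE)
  }
  invisible(cohort)
}

#' Write / read a cohort as delimited text
#'
#' The cohort is stored as two UTF-8 comma-separated files with header
#' rows: a values matrix (`subject_id` plus one column per region) and a
#' phenotype table (`subject_id`, `group`, `age`, `sex`, `glucose`).
#'
#' @param cohort A `metab_cohort` tibble.
#' @param values_path,phenotype_path Output/input file paths.
#' @return `write_cohort()` returns the input invisibly; `read_cohort()`
#'   returns a `metab_cohort` tibble.
#' @export
write_cohort <- function(cohort, values_path, phenotype_path) {
  mn_check_cohort(cohort)
  vals <- mn_value_matrix(cohort)
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(subject_id = cohort$subject_id),
                     tibble::as_tibble(vals)),
    values_path)
  readr::write_csv(
    dplyr::select(tibble::as_tibble(cohort), "subject_id", "group",
                  "age", "sex", "glucose"),
    phenotype_path)
  invisible(cohort)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(values_path, phenotype_path) {
  vals <- readr::read_csv(values_path, show_col_types = FALSE)
  pheno <- readr::read_csv(phenotype_path, show_col_types = FALSE)
  if (!identical(vals$subject_id, pheno$subject_id)) {
    stop("subject_id mismatch between values and phenotype files",
         call. = FALSE)
  }
  regions <- setdiff(names(vals), "subject_id")
  out <- dplyr::bind_cols(pheno, vals[regions])
  out <- structure(out,
                   region_names = regions,
                   class = c("metab_cohort", class(out)))
  mn_check_cohort(out)
  out
}
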