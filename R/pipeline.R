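# End-to-end orchestration: configuration, staged execution with a
# manifest, and report rendering from a completed run directory.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end run. Either point
#' `values_path`/`phenotype_path` at delimited cohort files (see
#' [write_cohort()]) or supply a [cohort_spec()] to simulate the cohort.
#'
#' @param out_dir Output directory for all artifacts.
#' @param values_path,phenotype_path Cohort input files (optional if
#'   `spec` given).
#' @param spec A [cohort_spec()] used when no input files are given.
#' @param density_start,density_stop,density_step Density sweep (defaults
#'   0.10, 0.40, 0.01).
#' @param rank Edge ranking rule, `"signed"` or `"absolute"`.
#' @param hub_threshold Hub cutoff on normalized betweenness (default 1.5).
#' @param hub_density Density at which hub tables are computed; `NA`
#'   (default) uses the minimum fully-connected density of the sweep.
#' @param reps Permutations for the group tests (default 1000).
#' @param n_random Reference-ensemble size for small-world curves
#'   (default 100; set 0 to skip gamma/lambda/sigma).
#' @param test_metrics Scalar metrics passed to [permutation_test()]
#'   (default `c("cp", "lp")`).
#' @param test_bi Also run the region-wise betweenness permutation test
#'   at `hub_density` (default `FALSE`; costly).
#' @param covariates Nuisance covariates for [residualize()].
#' @param normalize_method `"region"` (default for tabular input) or
#'   `"voxel"`.
#' @param strict Refuse disconnected graphs (default `TRUE`).
#' @param seed Master seed for every stochastic stage.
#' @return A `run_config` object (a validated list).
#' @export
run_config <- function(out_dir,
                       values_path = NULL, phenotype_path = NULL,
                       spec = NULL,
                       density_start = 0.10, density_stop = 0.40,
                       density_step = 0.01,
                       rank = "signed",
                       hub_threshold = 1.5, hub_density = NA_real_,
                       reps = 1000L, n_random = 100L,
                       test_metrics = c("cp", "lp"), test_bi = FALSE,
                       covariates = c("age", "sex", "glucose"),
                       normalize_method = "region",
                       strict = TRUE, seed = 1L) {
  if (!(density_start > 0 && density_start < density_stop &&
        density_stop < 1)) {
    stop("need 0 < density_start < density_stop < 1", call. = FALSE)
  }
  if (density_step <= 0) stop("density_step must be > 0", call. = FALSE)
  if (reps < 1) stop("reps must be >= 1", call. = FALSE)
  if (is.null(spec) && (is.null(values_path) || is.null(phenotype_path))) {
    stop("supply either cohort file paths or a cohort_spec", call. = FALSE)
  }
  structure(list(
    out_dir = out_dir, values_path = values_path,
    phenotype_path = phenotype_path, spec = spec,
    density_start = density_start, density_stop = density_stop,
    density_step = density_step, rank = rank,
    hub_threshold = hub_threshold, hub_density = hub_density,
    reps = as.integer(reps), n_random = as.integer(n_random),
    test_metrics = test_metrics, test_bi = isTRUE(test_bi),
    covariates = covariates, normalize_method = normalize_method,
    strict = isTRUE(strict), seed = as.integer(seed)),
    class = "run_config")
}

#' Run the full metabolic-network pipeline
#'
#' Executes, in order: cohort load/simulation, whole-brain normalization,
#' covariate residualization, per-group correlation networks, the density
#' sweep with connectedness bookkeeping, metric curves (with small-world
#' indices when `n_random > 0`), permutation tests, hub tables, the
#' regional covariate-adjusted group contrast, and a JSON manifest. Every
#' tabular artifact is comma-separated UTF-8 with a header; a failed
#' stage aborts with the stage name and leaves a `FAILED` marker naming
#' it. Two runs from the same configuration produce byte-identical
#' tabular outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the run directory path.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  marker <- file.path(config$out_dir, "FAILED")
  if (file.exists(marker)) unlink(marker)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      writeLines(paste0("stage: ", name, "\n", conditionMessage(e)), marker)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    message(sprintf("[%s] done in %.1fs", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    res
  }
  densities <- seq(config$density_start, config$density_stop,
                   by = config$density_step)

  cohort <- stage("cohort", {
    if (!is.null(config$values_path)) {
      for (p in c(config$values_path, config$phenotype_path)) {
        if (!file.exists(p)) stop("input file not found: ", p,
                                  call. = FALSE)
      }
      read_cohort(config$values_path, config$phenotype_path)
    } else {
      co <- generate_cohort(config$spec)
      write_cohort(co, file.path(config$out_dir, "cohort_values.csv"),
                   file.path(config$out_dir, "cohort_phenotype.csv"))
      co
    }
  })

  residuals <- stage("preprocess", {
    norm <- normalize_whole_brain(cohort, method = config$normalize_method)
    res <- residualize(norm, covariates = config$covariates)
    readr::write_csv(tibble::as_tibble(as.data.frame(res)),
                     file.path(config$out_dir, "residuals.csv"))
    res
  })

  nets <- stage("networks", {
    groups <- sort(unique(residuals$group))
    nets <- lapply(stats::setNames(groups, groups), function(g) {
      net <- correlation_network(residuals, g)
      write_network(net, file.path(config$out_dir,
                                   paste0("correlation_", g, ".csv")))
      net
    })
    nets
  })

  sweeps <- stage("density_sweep", {
    sweeps <- lapply(nets, density_sweep, densities = densities,
                     rank = config$rank)
    conn <- purrr::imap_dfr(sweeps, function(sw, g) {
      dplyr::mutate(tidy(sw), group = g, .before = 1)
    })
    readr::write_csv(conn, file.path(config$out_dir, "connectedness.csv"))
    jsonlite::write_json(
      list(densities = densities, rank = config$rank,
           min_connected_density = lapply(sweeps, function(sw)
             attr(check_connectedness(sw), "min_connected_density"))),
      file.path(config$out_dir, "sweep_manifest.json"),
      auto_unbox = TRUE, digits = NA)
    sweeps
  })

  curves <- stage("metrics", {
    cv <- metric_curves(residuals, densities = densities,
                        rank = config$rank, n_random = config$n_random,
                        seed = config$seed + 2L, strict = config$strict)
    readr::write_csv(tibble::as_tibble(as.data.frame(cv)),
                     file.path(config$out_dir, "metric_curves.csv"))
    cv
  })

  perm <- stage("permutation_test", {
    pt <- permutation_test(residuals, metrics = config$test_metrics,
                           densities = densities, reps = config$reps,
                           seed = config$seed, rank = config$rank)
    readr::write_csv(tidy(pt),
                     file.path(config$out_dir, "permutation_tests.csv"))
    pt
  })

  hub_density <- config$hub_density
  if (is.na(hub_density)) {
    conn <- check_connectedness(sweeps[[1]])
    for (sw in sweeps[-1]) {
      conn2 <- check_connectedness(sw)
      conn$connected <- conn$connected & conn2$connected
    }
    if (!any(conn$connected)) {
      stop("no density in the sweep is fully connected for all groups",
           call. = FALSE)
    }
    hub_density <- min(conn$density[conn$connected])
  }

  hubs <- stage("hubs", {
    hubs <- purrr::imap(nets, function(net, g) {
      bn <- threshold_by_density(net, hub_density, rank = config$rank)
      classify_hubs(bn, threshold = config$hub_threshold, group = g)
    })
    hub_tab <- dplyr::bind_rows(hubs)
    hub_tab$hub_density <- hub_density
    readr::write_csv(hub_tab, file.path(config$out_dir, "hub_tables.csv"))
    if (length(hubs) == 2) {
      readr::write_csv(shared_hubs(hubs[[1]], hubs[[2]]),
                       file.path(config$out_dir, "shared_hubs.csv"))
    }
    hubs
  })

  if (config$test_bi) {
    stage("betweenness_test", {
      bi <- permutation_test(residuals, metrics = "bi",
                             densities = hub_density,
                             reps = config$reps,
                             seed = config$seed + 3L, rank = config$rank,
                             alternative = "two.sided")
      readr::write_csv(tidy(bi),
                       file.path(config$out_dir, "betweenness_tests.csv"))
    })
  }

  stage("contrast", {
    norm <- normalize_whole_brain(cohort, method = config$normalize_method)
    ct <- group_metabolic_contrast(norm, covariates = config$covariates,
                                   reps = config$reps,
                                   seed = config$seed + 1L)
    readr::write_csv(ct, file.path(config$out_dir, "group_contrast.csv"))
  })

  stage("manifest", {
    csvs <- sort(list.files(config$out_dir, pattern = "\\.csv$"))
    cfg <- config
    cfg$spec <- if (is.null(config$spec)) NULL else unclass(config$spec)
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("metabnet")),
           config = unclass(cfg),
           hub_density = hub_density,
           outputs = as.list(stats::setNames(
             unname(tools::md5sum(file.path(config$out_dir, csvs))), csvs))),
      file.path(config$out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, null = "null")
  })

  invisible(config$out_dir)
}

#' Render a report from a completed run directory
#'
#' Summarizes a [run_pipeline()] directory into a plain-text report
#' (`report.md`) and figure files: metric-vs-density curves with
#' significant densities marked, hub tables per group, the shared-hub
#' listing, and the regional contrast. Missing artifacts are noted in the
#' report, never fabricated.
#'
#' @param dir A run directory produced by [run_pipeline()].
#' @param figures Write PNG figures (default `TRUE`).
#' @return Invisibly, the report path.
#' @export
render_report <- function(dir, figures = TRUE) {
  path <- function(f) file.path(dir, f)
  lines <- c("# Metabolic network analysis report", "")
  have <- function(f) file.exists(path(f))

  if (have("permutation_tests.csv")) {
    pt <- readr::read_csv(path("permutation_tests.csv"),
                          show_col_types = FALSE)
    lines <- c(lines, "## Group differences (permutation test)", "")
    for (m in unique(pt$metric)) {
      sig <- pt$density[pt$metric == m & pt$significant]
      lines <- c(lines, sprintf(
        "- %s: %s", m,
        if (length(sig) == 0) "no significant densities" else
          sprintf("significant at densities %s",
                  paste(format(sig, trim = TRUE), collapse = ", "))))
    }
    lines <- c(lines, "")
  } else {
    lines <- c(lines, "Permutation results missing.", "")
  }

  if (have("hub_tables.csv")) {
    hubs <- readr::read_csv(path("hub_tables.csv"), show_col_types = FALSE)
    lines <- c(lines, "## Hub regions", "")
    for (g in unique(hubs$group)) {
      h <- hubs[hubs$group == g & hubs$hub, ]
      h <- h[order(-h$b), ]
      lines <- c(lines, sprintf("### %s (%d hubs)", g, nrow(h)),
                 if (nrow(h) == 0) "none" else
                   sprintf("- %s (b = %.2f)", h$region, h$b), "")
    }
    if (have("shared_hubs.csv")) {
      sh <- readr::read_csv(path("shared_hubs.csv"), show_col_types = FALSE)
      lines <- c(lines, sprintf("Shared hubs: %d%s", nrow(sh),
                                if (nrow(sh) == 0) " (none)" else
                                  paste0(" (", paste(sh$region,
                                                     collapse = ", "), ")")),
                 "")
    }
  } else {
    lines <- c(lines, "Hub tables missing.", "")
  }

  if (have("group_contrast.csv")) {
    ct <- readr::read_csv(path("group_contrast.csv"), show_col_types = FALSE)
    sig <- ct[ct$p_fwe < 0.05, ]
    lines <- c(lines, "## Regional metabolic contrast", "",
               sprintf("%d of %d regions significant after family-wise %s",
                       nrow(sig), nrow(ct), "permutation correction"),
               if (nrow(sig) > 0)
                 sprintf("- %s: estimate %.3f, t = %.2f, p_fwe = %.3f",
                         sig$region, sig$estimate, sig$t, sig$p_fwe), "")
  }

  if (figures && have("metric_curves.csv")) {
    cv <- readr::read_csv(path("metric_curves.csv"), show_col_types = FALSE)
    class(cv) <- c("metab_curves", class(cv))
    ggplot2::ggsave(path("metric_curves.png"), autoplot(cv),
                    width = 8, height = 5, dpi = 150)
  }

  writeLines(lines, path("report.md"))
  invisible(path("report.md"))
}
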