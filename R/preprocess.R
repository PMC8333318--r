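# Atlas extraction, whole-brain normalization, covariate residualization,
# and the ROI-level covariate-adjusted group contrast.

#' Mean regional signal from labelled volumes
#'
#' Averages each subject's voxel values within every atlas region. Label 0
#' is background; every other label in the atlas becomes one region.
#'
#' @param images A list of 3D numeric arrays, or a character vector of
#'   NIfTI file paths (read with RNifti), one per subject; all must share
#'   the atlas grid. Voxel-wise alignment is the caller's responsibility.
#' @param atlas A 3D integer array of region labels, or a NIfTI path.
#' @param region_names Optional labels for the regions, in ascending atlas
#'   label order; defaults to AAL abbreviations for 90 regions, otherwise
#'   `R<label>`.
#' @param subject_ids Optional subject identifiers (default `S001`, ...).
#' @return A tibble: `subject_id` plus one column per region, with
#'   attribute `region_sizes` (voxels per region) for use by
#'   [normalize_whole_brain()].
#' @export
extract_roi_means <- function(images, atlas, region_names = NULL,
                              subject_ids = NULL) {
  atlas <- mn_as_volume(atlas)
  labels <- sort(unique(as.integer(atlas[atlas != 0])))
  if (length(labels) == 0) stop("atlas has no foreground labels",
                                call. = FALSE)
  if (is.null(region_names)) {
    region_names <- if (length(labels) == 90L && all(labels == 1:90)) {
      mn_region_names(90L)
    } else {
      paste0("R", labels)
    }
  }
  if (length(region_names) != length(labels)) {
    stop("`region_names` must have one entry per foreground label",
         call. = FALSE)
  }
  if (is.character(images)) images <- as.list(images)
  n_sub <- length(images)
  if (is.null(subject_ids)) subject_ids <- sprintf("S%03d", seq_len(n_sub))

  lab_vec <- as.integer(as.vector(atlas))
  fg <- lab_vec != 0L
  lab_fac <- factor(lab_vec[fg], levels = labels)
  sizes <- as.integer(table(lab_fac))
  names(sizes) <- region_names

  means <- matrix(NA_real_, n_sub, length(labels),
                  dimnames = list(subject_ids, region_names))
  for (s in seq_len(n_sub)) {
    img <- mn_as_volume(images[[s]])
    if (!identical(dim(img), dim(atlas))) {
      stop(sprintf("image %d grid %s does not match atlas grid %s", s,
                   paste(dim(img), collapse = "x"),
                   paste(dim(atlas), collapse = "x")), call. = FALSE)
    }
    v <- as.vector(img)[fg]
    means[s, ] <- as.vector(rowsum(v, lab_fac)) / sizes
  }
  out <- dplyr::bind_cols(tibble::tibble(subject_id = subject_ids),
                          tibble::as_tibble(means))
  structure(out, region_names = region_names, region_sizes = sizes,
            class = c("metab_cohort", class(out)))
}

mn_as_volume <- function(x) {
  if (is.character(x)) {
    rlang::check_installed("RNifti", reason = "to read NIfTI volumes")
    x <- RNifti::asNifti(RNifti::readNifti(x))
  }
  a <- unclass(as.array(x))
  if (length(dim(a)) != 3L) stop("volumes must be 3D arrays", call. = FALSE)
  a
}

#' Normalize regional values by the whole-brain mean
#'
#' Divides each subject's regional means by that subject's whole-brain
#' mean, removing global metabolic scale so that downstream correlations
#' reflect relative regional covariation. With `method = "voxel"` the
#' whole-brain mean is the voxel-count-weighted mean over atlas foreground
#' (the mean over all in-atlas voxels); `"region"` uses the unweighted
#' mean of the regional means. Voxel weighting is the default whenever
#' region sizes are available.
#'
#' @param cohort A cohort tibble (or anything with region columns and a
#'   `subject_id` column).
#' @param region_sizes Optional named voxel counts per region; taken from
#'   the cohort's `region_sizes` attribute when present.
#' @param method `"voxel"` or `"region"`; defaults to `"voxel"` when sizes
#'   are available, `"region"` otherwise.
#' @return The cohort with region columns replaced by normalized values
#'   (dimensionless; a subject uniform across regions maps to all 1s).
#' @export
normalize_whole_brain <- function(cohort, region_sizes = NULL,
                                  method = NULL) {
  vals <- mn_value_matrix(cohort)
  if (is.null(region_sizes)) region_sizes <- attr(cohort, "region_sizes")
  if (is.null(method)) {
    method <- if (is.null(region_sizes)) "region" else "voxel"
  }
  method <- match.arg(method, c("voxel", "region"))
  w <- if (method == "voxel") {
    if (is.null(region_sizes)) {
      stop("`method = \"voxel\"` requires region voxel counts", call. = FALSE)
    }
    sz <- region_sizes[colnames(vals)]
    if (anyNA(sz)) stop("region_sizes missing for some regions",
                        call. = FALSE)
    sz / sum(sz)
  } else {
    rep(1 / ncol(vals), ncol(vals))
  }
  wb <- as.vector(vals %*% w)
  if (any(wb <= 0)) {
    stop("non-positive whole-brain mean for subject(s): ",
         paste(cohort$subject_id[wb <= 0], collapse = ", "), call. = FALSE)
  }
  out <- cohort
  out[, colnames(vals)] <- tibble::as_tibble(vals / wb)
  out
}

# Design matrix for covariate adjustment; errors name collinear columns.
mn_design <- function(cohort, covariates) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss)) {
    stop("covariates not found in cohort: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  X <- cbind(`(Intercept)` = 1,
             as.matrix(as.data.frame(cohort)[, covariates, drop = FALSE]))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  X
}

#' Residualize regional values on nuisance covariates
#'
#' Regresses each region's (normalized) values on an intercept plus the
#' covariates by ordinary least squares and keeps the residuals, removing
#' linear age, sex and fasting-glucose effects before network
#' construction. By default the regression pools both groups in a single
#' design with no group term, so genuine between-group differences
#' survive into the correlation stage; `by_group = TRUE` fits each group
#' separately for sensitivity analyses.
#'
#' @param cohort A cohort tibble with covariate columns.
#' @param covariates Covariate column names (default age, sex, glucose).
#' @param by_group Fit separate regressions per group (default `FALSE`).
#' @return A tibble of class `metab_residuals`: `subject_id`, `group`,
#'   plus one residual column per region (each mean-zero across the
#'   subjects entering its regression). Attribute `model_terms` records
#'   the covariates used.
#' @export
residualize <- function(cohort, covariates = c("age", "sex", "glucose"),
                        by_group = FALSE) {
  mn_check_cohort(cohort)
  vals <- mn_value_matrix(cohort)
  res <- matrix(NA_real_, nrow(vals), ncol(vals),
                dimnames = dimnames(vals))
  if (by_group) {
    for (g in unique(cohort$group)) {
      idx <- cohort$group == g
      X <- mn_design(cohort[idx, ], covariates)
      res[idx, ] <- stats::lm.fit(X, vals[idx, , drop = FALSE])$residuals
    }
  } else {
    X <- mn_design(cohort, covariates)
    res[, ] <- stats::lm.fit(X, vals)$residuals
  }
  out <- dplyr::bind_cols(
    tibble::tibble(subject_id = cohort$subject_id, group = cohort$group),
    tibble::as_tibble(res))
  structure(out,
            region_names = colnames(vals),
            model_terms = covariates,
            class = c("metab_residuals", class(out)))
}

#' Covariate-adjusted regional group contrast
#'
#' Per region, fits `value ~ group + covariates` and reports the
#' patient-vs-control coefficient, its t statistic and two-sided p value,
#' plus a permutation-based family-wise-adjusted p value: group labels
#' are shuffled `reps` times (covariates fixed), the maximum absolute t
#' across regions forms the null, and each region's adjusted p is the
#' add-one tail probability of that max-|t| null.
#'
#' @param cohort A (normalized) cohort tibble.
#' @param covariates Covariate column names.
#' @param reps Label permutations for family-wise control (default 1000).
#' @param seed Optional seed for the permutation stream.
#' @return A tibble: `region`, `estimate` (patient minus control, adjusted),
#'   `t`, `p`, `p_fwe`.
#' @export
group_metabolic_contrast <- function(cohort,
                                     covariates = c("age", "sex", "glucose"),
                                     reps = 1000L, seed = NULL) {
  mn_check_cohort(cohort)
  if (!is.null(seed)) set.seed(seed)
  vals <- mn_value_matrix(cohort)
  grp <- as.numeric(cohort$group == "patient")
  Xcov <- mn_design(cohort, covariates)

  tstat <- function(g) {
    X <- cbind(Xcov, group = g)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      stop("design matrix is rank deficient; collinear column(s): group",
           call. = FALSE)
    }
    fit <- stats::lm.fit(X, vals)
    df <- nrow(X) - ncol(X)
    sigma2 <- colSums(fit$residuals^2) / df
    xtxinv_gg <- chol2inv(qr.R(qx))[ncol(X), ncol(X)]
    beta_g <- fit$coefficients["group", ]
    list(est = beta_g, t = beta_g / sqrt(sigma2 * xtxinv_gg), df = df)
  }

  obs <- tstat(grp)
  null_max <- vapply(seq_len(reps), function(r) {
    max(abs(tstat(sample(grp))$t))
  }, numeric(1))
  p_fwe <- vapply(abs(obs$t), function(t0) {
    (sum(null_max >= t0) + 1) / (reps + 1)
  }, numeric(1))

  tibble::tibble(
    region = colnames(vals),
    estimate = unname(obs$est),
    t = unname(obs$t),
    p = 2 * stats::pt(abs(obs$t), df = obs$df, lower.tail = FALSE),
    p_fwe = p_fwe
  )
}
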