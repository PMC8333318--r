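test_that("extract_roi_means matches trivial and brute-force volumes", {
  atlas <- array(0L, c(4, 4, 4))
  atlas[2:3, 2:3, 1:4] <- rep(1:4, each = 4)

  const <- array(7, c(4, 4, 4))
  out <- extract_roi_means(list(const), atlas)
  expect_equal(unname(unlist(out[1, -1])), rep(7, 4))

  labs <- array(as.numeric(atlas), dim(atlas))
  out2 <- extract_roi_means(list(labs), atlas)
  expect_equal(unname(unlist(out2[1, -1])), 1:4)

  # brute-force per-voxel accumulation oracle on a random volume
  set.seed(1)
  img <- array(rnorm(8^3), c(8, 8, 8))
  atl <- array(sample(0:5, 8^3, replace = TRUE), c(8, 8, 8))
  out3 <- extract_roi_means(list(img), atl)
  for (lab in 1:5) {
    expect_equal(out3[[paste0("R", lab)]][1],
                 sum(img[atl == lab]) / sum(atl == lab), tolerance = 1e-12)
  }
})

test_that("extract_roi_means rejects mismatched grids", {
  atlas <- array(1L, c(3, 3, 3))
  img <- array(0, c(3, 3, 4))
  expect_error(extract_roi_means(list(img), atlas), "grid")
})

test_that("extraction recovers a cohort from synthetic NIfTI volumes", {
  skip_if_not_installed("RNifti")
  co <- generate_cohort(cohort_spec(n_per_group = 3, n_regions = 6,
                                    seed = 8))
  dir <- withr::local_tempdir()
  paths <- write_cohort_volumes(co, dir)
  got <- extract_roi_means(paths$image_paths, paths$atlas_path,
                           region_names = attr(co, "region_names"),
                           subject_ids = co$subject_id)
  expect_equal(unname(as.matrix(got[, -1])),
               unname(metabnet:::mn_value_matrix(co)), tolerance = 1e-6)
  expect_equal(unname(attr(got, "region_sizes")), rep(16L, 6))
})

test_that("whole-brain normalization uses voxel-weighted means", {
  vals <- tibble::tibble(subject_id = "S1", R1 = 2, R2 = 4, R3 = 6)
  out <- normalize_whole_brain(vals, region_sizes = c(R1 = 1, R2 = 1,
                                                      R3 = 2),
                               method = "voxel")
  # whole-brain mean (2 + 4 + 6*2) / 4 = 4.5
  expect_equal(unname(unlist(out[1, c("R1", "R2", "R3")])),
               c(2, 4, 6) / 4.5, tolerance = 1e-12)
})

test_that("normalization maps uniform subjects to 1 and is scale-free", {
  co <- generate_cohort(cohort_spec(n_per_group = 6, n_regions = 8,
                                    seed = 3))
  uni <- co
  regions <- attr(co, "region_names")
  uni[, regions] <- 5
  expect_equal(unname(as.matrix(normalize_whole_brain(uni)[, regions])),
               matrix(1, nrow(co), 8))

  norm1 <- normalize_whole_brain(co)
  scaled <- co
  set.seed(4)
  s <- runif(nrow(co), 0.5, 4) # per-subject global rescale
  scaled[, regions] <- metabnet:::mn_value_matrix(co) * s
  norm2 <- normalize_whole_brain(scaled)
  expect_equal(as.matrix(norm2[, regions]), as.matrix(norm1[, regions]),
               tolerance = 1e-12)
})

test_that("normalization refuses non-positive whole-brain means", {
  vals <- tibble::tibble(subject_id = "S1", R1 = -2, R2 = 1)
  expect_error(normalize_whole_brain(vals), "S1")
})

test_that("residualize removes exact linear covariate effects", {
  co <- generate_cohort(cohort_spec(n_per_group = 10, n_regions = 6,
                                    seed = 6))
  regions <- attr(co, "region_names")
  crafted <- co
  for (r in regions) crafted[[r]] <- 2 * co$age + 3 * co$sex +
    1 * co$glucose + 5
  res <- residualize(crafted)
  expect_lt(max(abs(metabnet:::mn_value_matrix(res))), 1e-8)
})

test_that("residuals are column-centred, design-orthogonal, idempotent", {
  co <- generate_cohort(cohort_spec(n_per_group = 15, n_regions = 10,
                                    seed = 7))
  res <- residualize(co)
  m <- metabnet:::mn_value_matrix(res)
  expect_lt(max(abs(colMeans(m))), 1e-10 * max(abs(m)))
  X <- metabnet:::mn_design(co, c("age", "sex", "glucose"))
  crossed <- crossprod(X, m)
  norms <- outer(sqrt(colSums(X^2)), sqrt(colSums(m^2)))
  expect_lt(max(abs(crossed / norms)), 1e-8)
  res2 <- residualize(res, covariates = character(0))
  # intercept-only second pass: residuals already centred, unchanged
  expect_equal(metabnet:::mn_value_matrix(res2), m, tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  co <- generate_cohort(cohort_spec(n_per_group = 6, n_regions = 5,
                                    seed = 2))
  co$age2 <- 2 * co$age
  expect_error(residualize(co, covariates = c("age", "age2")), "age2")
})

test_that("OLS recovers injected covariate betas within sampling error", {
  spec <- cohort_spec(n_per_group = 50, n_regions = 30,
                      covariate_betas = c(age = 0.05, sex = 0.4,
                                          glucose = 0.3),
                      noise_sd = 1, seed = 21)
  co <- generate_cohort(spec)
  vals <- metabnet:::mn_value_matrix(co)
  hits <- 0
  for (r in seq_len(ncol(vals))) {
    fit <- summary(lm(vals[, r] ~ age + sex + glucose,
                      data = as.data.frame(co)))
    est <- fit$coefficients[c("age", "sex", "glucose"), ]
    ok <- abs(est[, "Estimate"] - c(0.05, 0.4, 0.3)) <=
      3 * est[, "Std. Error"]
    hits <- hits + all(ok)
  }
  expect_gte(hits / ncol(vals), 0.9)
})

test_that("group contrast detects an injected shift and respects the null", {
  spec <- cohort_spec(n_per_group = 30, n_regions = 12, patient_effect = 0,
                      covariance_model = "shared", noise_sd = 0.5,
                      seed = 31)
  co <- generate_cohort(spec)
  regions <- attr(co, "region_names")
  shifted <- co
  shifted[[regions[1]]] <- co[[regions[1]]] +
    ifelse(co$group == "patient", 3 * 0.5, 0)
  ct <- group_metabolic_contrast(shifted, reps = 200, seed = 5)
  expect_lt(ct$p_fwe[1], 0.05)
  expect_gt(ct$estimate[1], 0)

  # shuffling labels before testing destroys the effect
  set.seed(99)
  broken <- shifted
  broken$group <- sample(broken$group)
  ct0 <- group_metabolic_contrast(broken, reps = 200, seed = 6)
  expect_gt(ct0$p_fwe[1], 0.05)
})
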