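# Synthetic volumetric companions to a cohort: a block atlas and
# per-subject volumes whose regional means reproduce the cohort table.
# These exist to exercise the NIfTI extraction path without real images.

#' Synthetic block atlas
#'
#' Builds a labelled 3D volume in which each region occupies one
#' `nx x ny` slab along the z axis, wrapped in a one-voxel background
#' border (label 0). Purely synthetic geometry — a stand-in for an
#' anatomical parcellation, useful only for testing extraction.
#'
#' @param n_regions Number of foreground labels (1..n_regions).
#' @param slab_dim Within-slab grid as `c(nx, ny)` (default `c(4, 4)`,
#'   16 voxels per region).
#' @return A 3D integer array with attribute `label_map` (label ->
#'   region name).
#' @export
synthetic_atlas <- function(n_regions, slab_dim = c(4L, 4L)) {
  nx <- slab_dim[1]; ny <- slab_dim[2]
  core <- array(rep(seq_len(n_regions), each = nx * ny),
                dim = c(nx, ny, n_regions))
  vol <- array(0L, dim = dim(core) + 2L)
  vol[2:(nx + 1), 2:(ny + 1), 2:(n_regions + 1)] <- core
  structure(vol, label_map = stats::setNames(mn_region_names(n_regions),
                                             seq_len(n_regions)))
}

#' Write a cohort as synthetic NIfTI volumes plus an atlas
#'
#' Renders each subject of a cohort as a 3D volume over
#' [synthetic_atlas()] geometry: every voxel of region r carries the
#' subject's value for region r, optionally plus voxel-level Gaussian
#' noise (noise is mean-zero within regions only in expectation).
#' Extraction with [extract_roi_means()] recovers the cohort table
#' exactly when `voxel_noise_sd = 0`.
#'
#' @param cohort A cohort tibble.
#' @param dir Output directory (created if needed).
#' @param voxel_noise_sd Within-region voxel noise SD (default 0).
#' @param seed Optional seed for the voxel noise.
#' @return Invisibly, a list with `atlas_path` and `image_paths`.
#' @export
write_cohort_volumes <- function(cohort, dir, voxel_noise_sd = 0,
                                 seed = NULL) {
  rlang::check_installed("RNifti", reason = "to write NIfTI volumes")
  if (!is.null(seed)) set.seed(seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vals <- mn_value_matrix(cohort)
  atlas <- synthetic_atlas(ncol(vals))
  atlas_path <- file.path(dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas), atlas_path)
  lab <- as.vector(atlas)
  image_paths <- character(nrow(vals))
  for (s in seq_len(nrow(vals))) {
    vox <- numeric(length(lab))
    vox[lab != 0] <- vals[s, lab[lab != 0]]
    if (voxel_noise_sd > 0) {
      vox[lab != 0] <- vox[lab != 0] +
        stats::rnorm(sum(lab != 0), sd = voxel_noise_sd)
    }
    img <- array(vox, dim = dim(atlas))
    image_paths[s] <- file.path(dir, paste0(cohort$subject_id[s], ".nii.gz"))
    RNifti::writeNifti(RNifti::asNifti(img), image_paths[s])
  }
  invisible(list(atlas_path = atlas_path, image_paths = image_paths))
}
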