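#' Describe a volumetric phantom
#'
#' Geometry and tissue values for a synthetic parcellated brain phantom: a
#' cuboidal white-matter core wrapped in a gray-matter shell ("ribbon") of
#' configurable thickness, the shell cut into angular-sector parcels about
#' the through-slice axis so every parcel has a WM-adjacent border. The
#' phantom stands in for a Freesurfer-style parcellation plus co-registered
#' quantitative MWF and T1 maps on a shared voxel grid.
#'
#' @param grid_shape Integer length-3, voxels per axis.
#' @param voxel_size_mm Isotropic voxel spacing in mm (default 1.2).
#' @param n_regions Number of cortical parcels tiling the shell.
#' @param ribbon_thickness_voxels Shell thickness in voxels.
#' @param mwf_wm,t1_wm_ms MWF (fraction) and T1 (ms) of the WM core.
#' @param mwf_gm,t1_gm_ms Per-parcel GM values; scalars are recycled to
#'   \code{n_regions}.
#' @param noise_sd Gaussian noise SD added to the MWF map inside the brain
#'   (the T1 map receives noise scaled by \code{t1_noise_sd}).
#' @param t1_noise_sd Gaussian noise SD for the T1 map, ms.
#' @param background_voxels Background margin around the shell, voxels.
#' @return An object of class \code{"phantom_spec"}.
#' @export
phantom_spec <- function(grid_shape = c(24, 24, 24), voxel_size_mm = 1.2,
                         n_regions = 4, ribbon_thickness_voxels = 3,
                         mwf_wm = 0.12, t1_wm_ms = 900,
                         mwf_gm = 0.05, t1_gm_ms = 1400,
                         noise_sd = 0, t1_noise_sd = 0,
                         background_voxels = 2) {
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 4),
            voxel_size_mm > 0, n_regions >= 1,
            ribbon_thickness_voxels >= 1, noise_sd >= 0, t1_noise_sd >= 0,
            mwf_wm >= 0, mwf_wm <= 1, all(mwf_gm >= 0), all(mwf_gm <= 1),
            t1_wm_ms > 0, all(t1_gm_ms > 0))
  structure(list(grid_shape = as.integer(grid_shape),
                 voxel_size_mm = voxel_size_mm,
                 n_regions = as.integer(n_regions),
                 ribbon_thickness_voxels = as.integer(ribbon_thickness_voxels),
                 mwf_wm = mwf_wm, t1_wm_ms = t1_wm_ms,
                 mwf_gm = rep_len(mwf_gm, n_regions),
                 t1_gm_ms = rep_len(t1_gm_ms, n_regions),
                 noise_sd = noise_sd, t1_noise_sd = t1_noise_sd,
                 background_voxels = as.integer(background_voxels)),
            class = "phantom_spec")
}

#' Generate a parcellated phantom with quantitative maps
#'
#' Builds the integer label volume (0 background, 1 WM core, 2..n+1 GM
#' parcels), a piecewise-constant MWF map and a piecewise-constant T1 map,
#' optionally with additive Gaussian noise inside the brain, all sharing a
#' diagonal voxel-to-world affine.
#'
#' @param spec A [phantom_spec()].
#' @param seed Optional integer seed (only relevant when noise is on).
#' @return A list of class \code{"mwf_phantom"} with elements
#'   \code{labels} (3-D integer array), \code{mwf}, \code{t1} (3-D numeric
#'   arrays), \code{affine} (4x4), \code{label_table} (data frame with
#'   \code{label}, \code{region}, \code{hemisphere}, \code{tissue_class}),
#'   and \code{spec}.
#' @export
#' @examples
#' ph <- simulate_phantom(phantom_spec(n_regions = 2))
#' table(ph$labels)
simulate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(seed)) set.seed(seed)
  d <- spec$grid_shape
  bg <- spec$background_voxels
  rib <- spec$ribbon_thickness_voxels
  # outer brain box and inner WM core box, per axis
  lo_out <- rep(bg + 1L, 3); hi_out <- d - bg
  lo_in <- lo_out + rib; hi_in <- hi_out - rib
  if (any(hi_in < lo_in))
    stop("ribbon thicker than grid: no room left for a white-matter core")
  labels <- array(0L, dim = d)
  ix <- slice.index(labels, 1); iy <- slice.index(labels, 2)
  iz <- slice.index(labels, 3)
  in_outer <- ix >= lo_out[1] & ix <= hi_out[1] &
    iy >= lo_out[2] & iy <= hi_out[2] & iz >= lo_out[3] & iz <= hi_out[3]
  in_core <- ix >= lo_in[1] & ix <= hi_in[1] &
    iy >= lo_in[2] & iy <= hi_in[2] & iz >= lo_in[3] & iz <= hi_in[3]
  labels[in_core] <- 1L
  shell <- in_outer & !in_core
  # angular sectors about the z axis through the grid centre
  cx <- (lo_out[1] + hi_out[1]) / 2; cy <- (lo_out[2] + hi_out[2]) / 2
  ang <- atan2(iy - cy, ix - cx) %% (2 * pi)
  sector <- as.integer(pmin(floor(ang / (2 * pi / spec$n_regions)),
                            spec$n_regions - 1L))
  labels[shell] <- 2L + sector[shell]
  mwf <- array(0, dim = d)
  t1 <- array(0, dim = d)
  mwf[labels == 1L] <- spec$mwf_wm
  t1[labels == 1L] <- spec$t1_wm_ms
  for (k in seq_len(spec$n_regions)) {
    mwf[labels == k + 1L] <- spec$mwf_gm[k]
    t1[labels == k + 1L] <- spec$t1_gm_ms[k]
  }
  brain <- labels > 0L
  if (spec$noise_sd > 0)
    mwf[brain] <- pmin(pmax(mwf[brain] +
      stats::rnorm(sum(brain), 0, spec$noise_sd), 0), 1)
  if (spec$t1_noise_sd > 0)
    t1[brain] <- pmax(t1[brain] + stats::rnorm(sum(brain), 0, spec$t1_noise_sd),
                      1e-3)
  affine <- diag(c(rep(spec$voxel_size_mm, 3), 1))
  label_table <- data.frame(
    label = c(1L, seq_len(spec$n_regions) + 1L),
    region = c("wm_core", sprintf("parcel%02d", seq_len(spec$n_regions))),
    hemisphere = c(NA_character_, rep("left", spec$n_regions)),
    tissue_class = c("wm", rep("gm", spec$n_regions)),
    stringsAsFactors = FALSE)
  structure(list(labels = labels, mwf = mwf, t1 = t1, affine = affine,
                 label_table = label_table, spec = spec),
            class = "mwf_phantom")
}

#' @export
print.mwf_phantom <- function(x, ...) {
  cat(sprintf("Phantom %s voxels @ %.2f mm, %d parcels + WM core (%d brain voxels)\n",
              paste(dim(x$labels), collapse = "x"), x$spec$voxel_size_mm,
              x$spec$n_regions, sum(x$labels > 0)))
  invisible(x)
}

#' Read and write phantom volumes as NIfTI-1
#'
#' Writes the label volume and quantitative maps of a phantom as
#' \code{.nii.gz} files plus the label table as TSV, and reads them back.
#' Voxel spacing is carried in the NIfTI header.
#'
#' @param phantom An \code{"mwf_phantom"}.
#' @param dir Output directory (created if missing).
#' @return \code{write_phantom} returns the vector of file paths invisibly;
#'   \code{read_phantom} returns an \code{"mwf_phantom"}-like list (without
#'   the generating \code{spec}).
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  vox <- rep(phantom$spec$voxel_size_mm %||% phantom$affine[1, 1], 3)
  paths <- file.path(dir, c("labels.nii.gz", "mwf.nii.gz", "t1.nii.gz",
                            "label_table.tsv"))
  write_nifti_volume(phantom$labels, paths[1], vox)
  write_nifti_volume(phantom$mwf, paths[2], vox)
  write_nifti_volume(phantom$t1, paths[3], vox)
  utils::write.table(phantom$label_table, paths[4], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(dir) {
  labels <- read_nifti_volume(file.path(dir, "labels.nii.gz"))
  structure(list(
    labels = array(as.integer(round(labels$voxels)), dim = dim(labels$voxels)),
    mwf = read_nifti_volume(file.path(dir, "mwf.nii.gz"))$voxels,
    t1 = read_nifti_volume(file.path(dir, "t1.nii.gz"))$voxels,
    affine = labels$affine,
    label_table = utils::read.delim(file.path(dir, "label_table.tsv"),
                                    stringsAsFactors = FALSE)),
    class = "mwf_phantom")
}

write_nifti_volume <- function(voxels, path, voxel_size_mm) {
  im <- RNifti::asNifti(voxels)
  RNifti::pixdim(im) <- voxel_size_mm
  RNifti::writeNifti(im, path)
  invisible(path)
}

read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  list(voxels = array(as.numeric(im), dim = dim(im)),
       affine = structure(RNifti::xform(im), class = NULL),
       voxel_size_mm = RNifti::pixdim(im))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
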