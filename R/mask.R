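#' Convert Gaussian FWHM to standard deviation
#'
#' \eqn{\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2})}.
#'
#' @param fwhm_mm Full width at half maximum, mm (positive).
#' @return Standard deviation in mm.
#' @export
#' @examples
#' fwhm_to_sigma(4)   # 1.69864
fwhm_to_sigma <- function(fwhm_mm) {
  if (any(fwhm_mm <= 0)) stop("fwhm must be positive")
  fwhm_mm / (2 * sqrt(2 * log(2)))
}

# discrete 1-D Gaussian, truncated at `truncate` sigmas, unit sum
gaussian_kernel_1d <- function(sigma_vox, truncate = 4) {
  if (sigma_vox <= 0) return(1)
  r <- max(1L, ceiling(truncate * sigma_vox))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# zero-padded 1-D convolution of x with symmetric kernel k (odd length);
# direct (non-FFT) so that values outside the kernel reach are exactly zero
conv1_zero <- function(x, k) {
  if (length(k) == 1L) return(x * k)
  r <- (length(k) - 1L) %/% 2L
  xp <- c(rep(0, r), x, rep(0, r))
  full <- stats::filter(xp, k, method = "convolution", sides = 2)
  as.numeric(full[(r + 1L):(r + length(x))])
}

plane_axes <- function(plane) {
  switch(plane,
         axial = list(inplane = c(1L, 2L), slice = 3L),
         coronal = list(inplane = c(1L, 3L), slice = 2L),
         sagittal = list(inplane = c(2L, 3L), slice = 1L),
         stop("unknown plane: ", plane))
}

#' Blur a parcel mask with a 2-D in-plane Gaussian kernel
#'
#' Convolves a binary parcel mask slice-by-slice with a separable 2-D
#' Gaussian kernel of the given FWHM, the field's standard first step for
#' building an adjacent white-matter sampling region around a cortical
#' parcel. The kernel is truncated at \code{truncate} sigmas per axis and
#' normalized to unit sum, so within-slice mass is conserved (up to
#' zero-padding loss at the volume edge) and output weights lie in [0, 1].
#'
#' @param mask 3-D array, binary (logical or 0/1) parcel mask.
#' @param fwhm_mm Kernel FWHM in mm (default 4).
#' @param voxel_size_mm Voxel spacing, scalar (isotropic) or length-3, mm.
#' @param plane Anatomical plane of the 2-D kernel: \code{"axial"} (default),
#'   \code{"coronal"} or \code{"sagittal"}; slices are taken along the
#'   remaining axis.
#' @param truncate Kernel support radius in sigmas (default 4).
#' @return Numeric 3-D array of weights in [0, 1].
#' @export
blur_parcel_2d <- function(mask, fwhm_mm = 4, voxel_size_mm = 1.2,
                           plane = "axial", truncate = 4) {
  stopifnot(length(dim(mask)) == 3)
  m <- array(as.numeric(mask != 0), dim = dim(mask))
  if (sum(m) == 0) {
    warning("empty parcel mask; returning all-zero weights")
    return(m)
  }
  vox <- rep_len(voxel_size_mm, 3)
  ax <- plane_axes(plane)
  sigma_mm <- fwhm_to_sigma(fwhm_mm)
  k1 <- gaussian_kernel_1d(sigma_mm / vox[ax$inplane[1]], truncate)
  k2 <- gaussian_kernel_1d(sigma_mm / vox[ax$inplane[2]], truncate)
  perm <- c(ax$inplane, ax$slice)
  mp <- aperm(m, perm)
  for (s in seq_len(dim(mp)[3])) {
    slab <- mp[, , s]
    slab <- apply(slab, 2, conv1_zero, k = k1)            # along axis 1
    slab <- t(apply(slab, 1, conv1_zero, k = k2))         # along axis 2
    mp[, , s] <- slab
  }
  out <- aperm(mp, order(perm))
  pmin(pmax(out, 0), 1)
}

#' Restrict blurred weights to adjacent white matter
#'
#' Zeroes the blurred parcel weights at every voxel whose tissue class is
#' not white matter (removing the cortex itself and all non-brain voxels),
#' leaving the WM penumbra of the parcel as the sampling mask.
#'
#' @param blurred 3-D weight array from [blur_parcel_2d()].
#' @param labels 3-D integer label volume on the same grid.
#' @param label_table Data frame with columns \code{label} and
#'   \code{tissue_class} mapping labels to tissue (\code{"wm"} retained).
#' @param floor Weights must exceed this value somewhere in WM, else the
#'   parcel is deemed to have no adjacent white matter (default 1e-6).
#' @return 3-D weight array, zero outside white matter.
#' @export
adjacent_wm_mask <- function(blurred, labels, label_table, floor = 1e-6) {
  stopifnot(identical(dim(blurred), dim(labels)))
  wm_labels <- label_table$label[label_table$tissue_class == "wm"]
  w <- blurred
  w[!(labels %in% wm_labels)] <- 0
  if (max(w) <= floor)
    stop("region has no adjacent white matter (no WM voxel receives weight > ",
         floor, ")")
  w
}

#' Weighted mean of a quantitative map
#'
#' \eqn{\sum w v / \sum w} over a weight mask, the superposition step that
#' turns an adjacent-WM mask into a regional mean.
#'
#' @param map 3-D numeric array.
#' @param weights 3-D numeric array of the same shape.
#' @return Scalar weighted mean.
#' @export
weighted_mean_map <- function(map, weights) {
  stopifnot(identical(dim(map), dim(weights)))
  tw <- sum(weights)
  if (tw <= 0) stop("total weight is zero")
  sum(weights * map) / tw
}

#' Unweighted regional mean and SD over a parcel
#'
#' Mean and standard deviation of a quantitative map over the voxels
#' carrying one parcel label (no blurring), as used for cortical MWF and
#' regional T1.
#'
#' @param map 3-D numeric array.
#' @param labels 3-D integer label volume on the same grid.
#' @param label Integer label of the parcel.
#' @return Named numeric \code{c(mean =, sd =)} (SD is \code{NA} for a
#'   single-voxel parcel).
#' @export
cortical_regional_mean <- function(map, labels, label) {
  stopifnot(identical(dim(map), dim(labels)))
  v <- map[labels == label]
  if (length(v) == 0) stop("empty parcel: label ", label)
  c(mean = mean(v), sd = stats::sd(v))
}

#' Extract regional measures from a phantom or map set
#'
#' Runs the full regional extraction for every gray-matter parcel: the
#' unweighted cortical mean (and SD) of the MWF and T1 maps over the
#' parcel, and the adjacent white-matter mean of each map under the
#' blur-and-subtract mask.
#'
#' @param phantom An \code{"mwf_phantom"} (or any list with \code{labels},
#'   \code{mwf}, \code{t1}, \code{label_table} and either \code{spec} or an
#'   \code{affine} giving voxel size).
#' @param fwhm_mm,plane,truncate Passed to [blur_parcel_2d()].
#' @param binarize_threshold If non-\code{NULL}, the adjacent-WM weights are
#'   binarized at this threshold before averaging (sensitivity analysis);
#'   default \code{NULL} keeps the blurred weights.
#' @return Data frame with one row per GM parcel: \code{region},
#'   \code{hemisphere}, \code{label}, \code{n_voxels}, \code{cortical_mwf},
#'   \code{cortical_mwf_sd}, \code{adjacent_mwf}, \code{cortical_t1_ms},
#'   \code{adjacent_t1_ms}.
#' @export
extract_regional_measures <- function(phantom, fwhm_mm = 4, plane = "axial",
                                      truncate = 4,
                                      binarize_threshold = NULL) {
  vox <- if (!is.null(phantom$spec)) phantom$spec$voxel_size_mm
         else diag(phantom$affine)[1:3]
  gm <- phantom$label_table[phantom$label_table$tissue_class == "gm", ]
  rows <- vector("list", nrow(gm))
  for (i in seq_len(nrow(gm))) {
    lab <- gm$label[i]
    parcel <- phantom$labels == lab
    cm <- cortical_regional_mean(phantom$mwf, phantom$labels, lab)
    ct <- cortical_regional_mean(phantom$t1, phantom$labels, lab)
    w <- blur_parcel_2d(parcel, fwhm_mm, vox, plane, truncate)
    w <- adjacent_wm_mask(w, phantom$labels, phantom$label_table)
    if (!is.null(binarize_threshold))
      w <- (w >= binarize_threshold) * 1
    rows[[i]] <- data.frame(
      region = gm$region[i], hemisphere = gm$hemisphere[i], label = lab,
      n_voxels = sum(parcel),
      cortical_mwf = cm[["mean"]], cortical_mwf_sd = cm[["sd"]],
      adjacent_mwf = weighted_mean_map(phantom$mwf, w),
      cortical_t1_ms = ct[["mean"]],
      adjacent_t1_ms = weighted_mean_map(phantom$t1, w),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
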