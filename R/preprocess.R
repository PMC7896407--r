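#' Separable Gaussian smoothing of a 3-D volume
#'
#' Applies an axis-separable Gaussian kernel with
#' \eqn{\sigma = FWHM / (2\sqrt{2\ln 2})} per axis, truncated at
#' \eqn{4\sigma} and renormalized, with zero-padded boundaries.
#' `fwhm_mm = 0` returns the input unchanged.
#'
#' @param volume 3-D numeric array.
#' @param fwhm_mm smoothing kernel full width at half maximum, in mm;
#'   scalar (isotropic) or length 3.
#' @param voxel_size_mm voxel edge length in mm; scalar or length 3. An
#'   anisotropic voxel size with a scalar `fwhm_mm` is a configuration
#'   error.
#' @return smoothed array of the same dimensions.
#' @export
smooth_gaussian <- function(volume, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(volume)) == 3)
  if (any(fwhm_mm < 0) || any(voxel_size_mm <= 0))
    stop("fwhm must be >= 0 and voxel size > 0")
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  if (length(fwhm_mm) == 1) {
    if (length(unique(voxel_size_mm)) > 1)
      stop("anisotropic voxel size requires per-axis fwhm_mm (config error)")
    fwhm_mm <- rep(fwhm_mm, 3)
  }
  if (all(fwhm_mm == 0)) return(volume)
  out <- volume
  for (ax in 1:3) {
    sigma <- fwhm_mm[ax] / (2 * sqrt(2 * log(2))) / voxel_size_mm[ax]
    if (sigma == 0) next
    w <- gaussian_kernel_1d(sigma)
    out <- convolve_axis(out, w, ax)
  }
  out
}

# normalized 1-D Gaussian taps truncated at 4 sigma
gaussian_kernel_1d <- function(sigma_vox) {
  r <- ceiling(4 * sigma_vox)
  w <- exp(-((-r:r)^2) / (2 * sigma_vox^2))
  w / sum(w)
}

# zero-padded shift-and-add convolution along one axis
convolve_axis <- function(vol, w, axis) {
  d <- dim(vol)
  n <- d[axis]
  r <- (length(w) - 1L) / 2L
  out <- array(0, d)
  for (k in -r:r) {
    dst <- max(1L, 1L - k):min(n, n - k)
    if (length(dst) == 0 || dst[1] > dst[length(dst)]) next
    src <- dst + k
    wk <- w[k + r + 1L]
    if (axis == 1L) {
      out[dst, , ] <- out[dst, , ] + wk * vol[src, , , drop = FALSE]
    } else if (axis == 2L) {
      out[, dst, ] <- out[, dst, ] + wk * vol[, src, , drop = FALSE]
    } else {
      out[, , dst] <- out[, , dst] + wk * vol[, , src, drop = FALSE]
    }
  }
  out
}

#' Construct a masked voxel profile
#'
#' @param values numeric vector of in-mask intensities.
#' @param scaling one of `"raw"`, `"global"`, `"pons"`.
#' @param subject_id optional id.
#' @return object of class `voxel_profile`.
#' @export
voxel_profile <- function(values, scaling = c("raw", "global", "pons"),
                          subject_id = NA_character_) {
  scaling <- match.arg(scaling)
  if (!all(is.finite(values))) stop("profile values must be finite")
  if (scaling == "global" && abs(mean(values) - 1) > 1e-9)
    stop("globally scaled profile must have mean 1")
  structure(list(values = values, scaling = scaling,
                 subject_id = subject_id), class = "voxel_profile")
}

#' @export
print.voxel_profile <- function(x, ...) {
  cat("voxel_profile (", x$scaling, " scaling): ", length(x$values),
      " voxels\n", sep = "")
  invisible(x)
}

#' Scale a profile (or rows of a profile matrix) to its global mean
#'
#' Divides each subject's in-mask values by their mean so downstream
#' clustering reflects the regional pattern rather than overall severity;
#' the output has mean exactly 1 per subject (homogeneous of degree zero,
#' idempotent).
#'
#' @param x a `voxel_profile`, numeric vector, or subject x voxel matrix.
#' @return same shape as the input, tagged with `"global"` scaling.
#' @export
scale_global <- function(x) {
  if (inherits(x, "voxel_profile")) {
    m <- mean(x$values)
    if (!is.finite(m) || m <= 0) stop("non-positive mean (scaling error)")
    return(voxel_profile(x$values / m, "global", x$subject_id))
  }
  if (is.matrix(x)) {
    m <- rowMeans(x)
    if (any(!is.finite(m) | m <= 0))
      stop("non-positive mean profile (scaling error)")
    out <- x / m
    attr(out, "scaling") <- "global"
    return(out)
  }
  m <- mean(x)
  if (!is.finite(m) || m <= 0) stop("non-positive mean (scaling error)")
  structure(x / m, scaling = "global")
}

#' Scale a volume to a reference-region mean and mask to grey matter
#'
#' Divides all in-mask values by the mean signal of a reference region
#' (pons by default), the standard intensity normalization for assessing
#' hypometabolism against a control group.
#'
#' @param volume 3-D array (or subject x voxel matrix over the full grid).
#' @param atlas a `label_atlas`.
#' @param region_set reference set name, default `"pons"`.
#' @return for a single volume, a `voxel_profile` over `gm_mask` with
#'   `"pons"` scaling; for a matrix, a subject x gm-voxel matrix with a
#'   `scaling` attribute.
#' @export
scale_reference <- function(volume, atlas, region_set = "pons") {
  ref_ids <- regions_in_set(atlas, region_set)
  ref_lin <- which(atlas$labels %in% ref_ids)
  if (length(ref_lin) == 0) stop("empty reference region (scaling error)")
  gm_lin <- which(atlas$gm_mask)
  if (is.matrix(volume)) {
    ref_mean <- rowMeans(volume[, ref_lin, drop = FALSE])
    if (any(ref_mean <= 0))
      stop("non-positive reference mean (scaling error)")
    out <- volume[, gm_lin, drop = FALSE] / ref_mean
    attr(out, "scaling") <- "pons"
    return(out)
  }
  ref_mean <- mean(volume[ref_lin])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop("non-positive reference mean (scaling error)")
  voxel_profile(volume[gm_lin] / ref_mean, "pons")
}

#' Extract in-mask grey matter profiles from full-grid images
#'
#' Convenience wrapper: optional smoothing of each subject's volume,
#' masking to grey matter, and intensity scaling.
#'
#' @param images subject x voxel matrix over the full grid.
#' @param atlas a `label_atlas`.
#' @param scaling `"global"`, `"pons"`, or `"raw"`.
#' @param fwhm_mm smoothing kernel FWHM in mm (0 = none).
#' @return subject x gm-voxel matrix with a `scaling` attribute.
#' @export
gm_profiles <- function(images, atlas, scaling = c("global", "pons", "raw"),
                        fwhm_mm = 0) {
  scaling <- match.arg(scaling)
  if (fwhm_mm > 0) images <- smooth_images(images, atlas, fwhm_mm)
  gm_lin <- which(atlas$gm_mask)
  switch(scaling,
    raw = structure(images[, gm_lin, drop = FALSE], scaling = "raw"),
    global = scale_global(images[, gm_lin, drop = FALSE]),
    pons = scale_reference(images, atlas))
}

#' Smooth every row of a subject x voxel image matrix
#'
#' @inheritParams gm_profiles
#' @return matrix of the same shape.
#' @export
smooth_images <- function(images, atlas, fwhm_mm = 8) {
  out <- images
  for (i in seq_len(nrow(images))) {
    v <- array(images[i, ], dim = atlas$dims)
    out[i, ] <- as.vector(smooth_gaussian(v, fwhm_mm, atlas$voxel_size_mm))
  }
  out
}

#' Regional mean intensities
#'
#' Unweighted voxel means per atlas region, with the scaling tag of the
#' input propagated.
#'
#' @param x a `voxel_profile` (over `gm_mask`), a gm-masked matrix from
#'   [gm_profiles()]/[scale_reference()], or a full-grid 3-D array.
#' @param atlas a `label_atlas`.
#' @param region_ids regions to summarize; defaults to all non-pons
#'   regions. A requested region with no voxels available is a data error.
#' @return named vector (single subject) or subject x region matrix, with
#'   a `scaling` attribute.
#' @export
extract_regional_means <- function(x, atlas, region_ids = NULL) {
  reg <- atlas$regions
  if (is.null(region_ids))
    region_ids <- reg$region_id[reg$set != "pons"]
  if (!all(region_ids %in% reg$region_id)) stop("unknown region id")

  gm_lin <- which(atlas$gm_mask)
  lab_gm <- atlas$labels[gm_lin]

  values_matrix <- NULL
  scaling <- "raw"
  if (inherits(x, "voxel_profile")) {
    values_matrix <- matrix(x$values, 1)
    lab <- lab_gm
    scaling <- x$scaling
  } else if (is.matrix(x)) {
    scaling <- attr(x, "scaling") %||% "raw"
    if (ncol(x) == length(gm_lin)) {
      values_matrix <- x; lab <- lab_gm
    } else {
      values_matrix <- x; lab <- as.vector(atlas$labels)
    }
  } else {
    values_matrix <- matrix(as.vector(x), 1)
    lab <- as.vector(atlas$labels)
  }

  out <- sapply(region_ids, function(r) {
    sel <- which(lab == r)
    if (length(sel) == 0) stop("region ", r, " has no voxels (data error)")
    rowMeans(values_matrix[, sel, drop = FALSE])
  })
  if (is.null(dim(out))) out <- matrix(out, nrow = 1)
  colnames(out) <- as.character(region_ids)
  rownames(out) <- rownames(values_matrix)
  if (nrow(out) == 1 && !is.matrix(x)) out <- out[1, ]
  attr(out, "scaling") <- scaling
  out
}

#' Ratio of mean uptake between two region sets
#'
#' `(mean over numerator regions) / (mean over denominator regions)` of a
#' regional mean vector — e.g. the inferior-to-medial temporal uptake ratio
#' used to contrast limbic-predominant against typical patterns.
#'
#' @param regional named regional mean vector from
#'   [extract_regional_means()].
#' @param numerator,denominator region id vectors (non-empty).
#' @return scalar ratio.
#' @export
regional_ratio <- function(regional, numerator, denominator) {
  if (length(numerator) == 0 || length(denominator) == 0)
    stop("region sets must be non-empty")
  num <- regional[as.character(numerator)]
  den <- regional[as.character(denominator)]
  if (any(is.na(num)) || any(is.na(den)))
    stop("regional vector does not cover the requested regions")
  dm <- mean(den)
  if (dm <= 0) stop("non-positive denominator mean")
  mean(num) / dm
}

`%||%` <- function(a, b) if (is.null(a)) b else a
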