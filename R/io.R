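#' Write a synthetic cohort to disk
#'
#' Writes one NIfTI-1 volume per subject plus the atlas labels and grey
#' matter mask, the baseline and visit tables as CSV, and a JSON manifest
#' carrying the full configuration (including the seed) so the cohort can
#' be regenerated exactly.
#'
#' @param sim a `synthetic_cohort` from [generate_cross_sectional()].
#' @param out_dir output directory (created if needed).
#' @param visits optional `longitudinal_data` from
#'   [generate_longitudinal()].
#' @return invisibly, the manifest list (with a `files` element).
#' @export
write_cohort <- function(sim, out_dir, visits = NULL) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  if (!identical(rownames(sim$images), sim$cohort$subject_id))
    stop("subject ids of images and cohort table disagree (data error)")
  if (!is.null(visits) &&
      !all(visits$visits$subject_id %in% sim$cohort$subject_id))
    stop("visit table contains unknown subject ids (data error)")
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory (I/O error)")

  atlas <- sim$atlas
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, showWarnings = FALSE)
  files <- character(0)
  for (i in seq_len(nrow(sim$images))) {
    f <- file.path(img_dir, paste0(sim$cohort$subject_id[i], ".nii.gz"))
    vol <- array(sim$images[i, ], dim = atlas$dims)
    RNifti::writeNifti(RNifti::asNifti(vol, pixdim = rep(atlas$voxel_size_mm, 3)), f)
    files <- c(files, f)
  }
  f_atlas <- file.path(out_dir, "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(atlas$labels,
                                     pixdim = rep(atlas$voxel_size_mm, 3),
                                     datatype = "int16"), f_atlas)
  f_mask <- file.path(out_dir, "gm_mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(atlas$gm_mask),
                                           dim = atlas$dims),
                                     pixdim = rep(atlas$voxel_size_mm, 3),
                                     datatype = "uint8"), f_mask)
  utils::write.csv(sim$cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)
  utils::write.csv(atlas$regions, file.path(out_dir, "regions.csv"),
                   row.names = FALSE)
  if (!is.null(visits)) {
    utils::write.csv(visits$visits, file.path(out_dir, "visits.csv"),
                     row.names = FALSE)
    utils::write.csv(visits$events, file.path(out_dir, "events.csv"),
                     row.names = FALSE)
  }
  manifest <- sim$manifest
  manifest$voxel_size_mm <- atlas$voxel_size_mm
  manifest$grid_dims <- atlas$dims
  manifest$n_cortical <- sum(atlas$regions$set == "cortical")
  manifest$files <- c(files, f_atlas, f_mask)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return list with `images` (subject x voxel matrix), `cohort`,
#'   `regions`, `visits`/`events` (if present) and `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cohort <- utils::read.csv(file.path(dir, "cohort.csv"))
  regions <- utils::read.csv(file.path(dir, "regions.csv"))
  imgs <- lapply(cohort$subject_id, function(id) {
    as.vector(RNifti::readNifti(file.path(dir, "images",
                                          paste0(id, ".nii.gz"))))
  })
  images <- do.call(rbind, imgs)
  rownames(images) <- cohort$subject_id
  out <- list(images = images, cohort = cohort, regions = regions,
              atlas_labels = array(
                as.integer(RNifti::readNifti(file.path(dir, "atlas.nii.gz"))),
                dim = manifest$grid_dims),
              manifest = manifest)
  fv <- file.path(dir, "visits.csv")
  if (file.exists(fv)) out$visits <- utils::read.csv(fv)
  fe <- file.path(dir, "events.csv")
  if (file.exists(fe)) out$events <- utils::read.csv(fe)
  out
}

#' Regenerate a cohort from a written manifest
#'
#' Rebuilds the configuration from `manifest.json` and reruns the
#' generator, reproducing the cohort bit-exactly.
#'
#' @param dir cohort directory containing `manifest.json`.
#' @return a `synthetic_cohort`.
#' @export
regenerate_from_manifest <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cfgl <- manifest$config
  cfg <- cohort_config(
    n_cn = cfgl$n_cn, n_ad = cfgl$n_ad, n_mci = cfgl$n_mci,
    subtype_proportions_ad = unlist(cfgl$subtype_proportions_ad),
    subtype_proportions_mci = unlist(cfgl$subtype_proportions_mci),
    global_factor_sd = cfgl$global_factor_sd,
    severity_shape = cfgl$severity_shape,
    severity_mean_ad = cfgl$severity_mean_ad,
    severity_mean_mci = cfgl$severity_mean_mci,
    voxel_noise_sd = cfgl$voxel_noise_sd,
    region_effect_sd = cfgl$region_effect_sd,
    n_region_modes = cfgl$n_region_modes,
    pons_bias_sd = cfgl$pons_bias_sd,
    reduction_cap = cfgl$reduction_cap,
    hazard_ratios = unlist(cfgl$hazard_ratios),
    baseline_hazard = cfgl$baseline_hazard,
    weibull_shape = cfgl$weibull_shape,
    decline_slopes = {
      m <- do.call(rbind, lapply(cfgl$decline_slopes, unlist))
      if (is.null(rownames(m))) rownames(m) <- c("MEM", "EF", "VS", "Lan")
      m
    },
    re_intercept_sd = cfgl$re_intercept_sd,
    re_slope_sd = cfgl$re_slope_sd,
    resid_sd = cfgl$resid_sd,
    followup_months = cfgl$followup_months,
    visit_interval_months = cfgl$visit_interval_months,
    seed = cfgl$seed)
  atlas <- generate_atlas(manifest$grid_dims,
                          n_cortical = manifest$n_cortical,
                          voxel_size_mm = manifest$voxel_size_mm)
  generate_cross_sectional(atlas, default_templates(atlas), cfg)
}
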