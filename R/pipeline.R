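#' Simulate a full synthetic study in one call
#'
#' Convenience wrapper: builds the default atlas and templates, draws the
#' cross-sectional cohort and, when MCI subjects are present, the
#' longitudinal visit data.
#'
#' @param config a [cohort_config()] (default configuration if omitted).
#' @param grid_dims,n_cortical,voxel_size_mm atlas parameters.
#' @param groups which groups to generate.
#' @param longitudinal draw visits/events for the MCI group.
#' @return a `synthetic_cohort` with an extra `longitudinal` element when
#'   requested, plus the `templates` used.
#' @export
simulate_cohort <- function(config = cohort_config(),
                            grid_dims = c(18L, 22L, 18L), n_cortical = 48L,
                            voxel_size_mm = 4,
                            groups = c("CN", "AD", "MCI"),
                            longitudinal = "MCI" %in% groups) {
  atlas <- generate_atlas(grid_dims, n_cortical, voxel_size_mm)
  templates <- default_templates(atlas)
  sim <- generate_cross_sectional(atlas, templates, config, groups = groups)
  sim$templates <- templates
  if (longitudinal && any(sim$cohort$group == "MCI"))
    sim$longitudinal <- generate_longitudinal(sim$cohort, config)
  sim
}

#' Fit the subtyping model on a dementia cohort
#'
#' The discovery stage of the pipeline: smooth all images, cluster the
#' globally scaled dementia profiles with Ward's linkage, select the number
#' of clusters by the silhouette criterion (Davies-Bouldin reported
#' alongside), compute subtype centroids, attach the CN regional reference
#' for the screen, and — for simulated data — name the recovered clusters
#' after the planted templates.
#'
#' @param sim a `synthetic_cohort` containing AD and CN subjects.
#' @param k_range candidate cluster numbers.
#' @param fwhm_mm smoothing kernel FWHM in mm applied before scaling.
#' @param k optionally force the number of clusters instead of the
#'   silhouette choice.
#' @return list of class `subtype_fit`: `solution` (a `cluster_solution`),
#'   `model` (a named `subtype_model`), `labels` (named subtype per AD
#'   subject), and `profiles` (the globally scaled AD profiles).
#' @export
fit_subtypes <- function(sim, k_range = 2:10, fwhm_mm = 8, k = NULL) {
  stopifnot(inherits(sim, "synthetic_cohort"))
  ad <- sim$cohort$group == "AD"
  cn <- sim$cohort$group == "CN"
  if (!any(ad)) stop("no AD subjects to cluster")
  images <- if (fwhm_mm > 0)
    smooth_images(sim$images, sim$atlas, fwhm_mm) else sim$images
  glob <- gm_profiles(images[ad, , drop = FALSE], sim$atlas, "global")
  sol <- select_k(glob, k_range)
  labels <- if (is.null(k)) sol$labels else cut_tree(sol$tree, k)
  cn_ref <- if (any(cn))
    cn_regional_reference(images[cn, , drop = FALSE], sim$atlas) else NULL
  model <- compute_centroids(glob, labels, cn_reference = cn_ref)
  if (!is.null(sim$templates))
    model <- match_subtype_names(model, sim$templates, sim$atlas)
  out <- list(solution = sol, model = model,
              labels = stats::setNames(model$subtypes[labels],
                                       sim$cohort$subject_id[ad]),
              profiles = glob)
  class(out) <- "subtype_fit"
  out
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat("subtype_fit: k =", x$solution$k, "\n")
  print(subtype_frequencies(x$labels), row.names = FALSE)
  invisible(x)
}
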