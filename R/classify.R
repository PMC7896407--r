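#' CN regional reference for the hypometabolism screen
#'
#' Mean and standard deviation of pons-scaled regional means in the
#' cognitively normal group, per cortical screening region.
#'
#' @param cn_images CN subject x voxel matrix over the full grid.
#' @param atlas a `label_atlas`.
#' @param region_ids regions to reference; defaults to the cortical set.
#' @param fwhm_mm optional smoothing applied before scaling.
#' @return data frame with `region_id`, `mean`, `sd`.
#' @export
cn_regional_reference <- function(cn_images, atlas, region_ids = NULL,
                                  fwhm_mm = 0) {
  region_ids <- region_ids %||% regions_in_set(atlas, "cortical")
  if (fwhm_mm > 0) cn_images <- smooth_images(cn_images, atlas, fwhm_mm)
  pons <- scale_reference(cn_images, atlas)
  rm <- extract_regional_means(pons, atlas, region_ids)
  data.frame(region_id = as.integer(colnames(rm)),
             mean = colMeans(rm), sd = apply(rm, 2, stats::sd))
}

#' Screen for regional hypometabolism
#'
#' A region is flagged when its pons-scaled mean lies at least one standard
#' deviation below the CN mean (inclusive boundary:
#' `value <= mean - sd`). A subject passes the screen when at least one
#' region is flagged; subjects with no flagged region belong to the
#' no-hypometabolism subtype.
#'
#' @param regional named regional mean vector (single subject) or subject x
#'   region matrix of pons-scaled regional means.
#' @param reference CN reference data frame (`region_id`, `mean`, `sd`),
#'   e.g. from [cn_regional_reference()] or a `subtype_model`.
#' @return data frame with `subject_id`, `n_flagged`, `passes_screen`, and
#'   attribute `z` (subject x region z-score matrix).
#' @export
screen_hypometabolism <- function(regional, reference) {
  if (inherits(reference, "subtype_model")) reference <- reference$cn_reference
  if (is.null(reference)) stop("no CN regional reference available")
  if (any(reference$sd <= 0)) stop("CN reference SDs must be positive")
  if (is.null(dim(regional))) regional <- matrix(
    regional, 1, dimnames = list("subject", names(regional)))
  need <- as.character(reference$region_id)
  if (!all(need %in% colnames(regional)))
    stop("regional vector does not cover all screened regions (data error)")
  vals <- regional[, need, drop = FALSE]
  z <- sweep(sweep(vals, 2, reference$mean), 2, reference$sd, "/")
  if (!all(is.finite(z))) stop("non-finite z-scores")
  flagged <- z <= -1          # inclusive boundary
  out <- data.frame(subject_id = rownames(vals) %||%
                      as.character(seq_len(nrow(vals))),
                    n_flagged = rowSums(flagged),
                    passes_screen = rowSums(flagged) > 0)
  rownames(out) <- NULL
  attr(out, "z") <- z
  out
}

#' Nearest-centroid subtype assignment
#'
#' Assigns each globally scaled profile to the subtype whose mean profile
#' has the smallest Euclidean distance. Exact ties are broken by the
#' model's fixed subtype order (first wins) and reported via the `tie`
#' column.
#'
#' @param profiles globally scaled voxel profile (vector) or subject x
#'   voxel matrix, voxel count matching the model centroids.
#' @param model a `subtype_model`.
#' @return data frame with `subject_id`, `subtype`, `tie`, and one
#'   `dist_<subtype>` column per subtype.
#' @export
classify_nearest_centroid <- function(profiles, model) {
  stopifnot(inherits(model, "subtype_model"))
  if (inherits(profiles, "voxel_profile")) profiles <- profiles$values
  if (is.null(dim(profiles)))
    profiles <- matrix(profiles, 1, dimnames = list("subject", NULL))
  if (ncol(profiles) != ncol(model$centroids))
    stop("profile length does not match centroids (data error)")
  cent <- model$centroids
  d2 <- outer(rowSums(profiles^2), rowSums(cent^2), "+") -
    2 * tcrossprod(profiles, cent)
  d2[d2 < 0] <- 0
  dist <- sqrt(d2)
  colnames(dist) <- model$subtypes
  pick <- apply(dist, 1, which.min)        # first minimum wins on ties
  tie <- apply(dist, 1, function(r) sum(r == min(r)) > 1)
  if (any(tie))
    message(sum(tie), " tie(s) in nearest-centroid assignment broken by ",
            "subtype order")
  out <- data.frame(subject_id = rownames(profiles) %||%
                      as.character(seq_len(nrow(profiles))),
                    subtype = model$subtypes[pick], tie = tie)
  dist_df <- as.data.frame(dist)
  names(dist_df) <- paste0("dist_", model$subtypes)
  rownames(out) <- NULL
  cbind(out, dist_df)
}

#' Two-stage classification of a prodromal cohort
#'
#' Applies the fully automated procedure: smooth, screen each subject for
#' regional hypometabolism on pons-scaled regional means against the CN
#' reference, then assign screen passers to the dementia-derived subtype
#' with the nearest globally scaled centroid. Subjects with no flagged
#' region are labelled `no_hypometabolism`.
#'
#' @param images subject x voxel matrix over the full grid.
#' @param atlas a `label_atlas`.
#' @param model a `subtype_model` with a CN reference.
#' @param fwhm_mm smoothing applied before both scalings (default 8 mm, as
#'   in standard FDG-PET preprocessing).
#' @return data frame with `subject_id`, `passes_screen`, `n_flagged`,
#'   `subtype` and per-subtype distance columns (NA for screen failures).
#' @export
classify_cohort <- function(images, atlas, model, fwhm_mm = 8) {
  stopifnot(inherits(model, "subtype_model"))
  if (nrow(images) == 0) {
    return(data.frame(subject_id = character(0),
                      passes_screen = logical(0), n_flagged = integer(0),
                      subtype = character(0)))
  }
  if (fwhm_mm > 0) images <- smooth_images(images, atlas, fwhm_mm)
  pons <- scale_reference(images, atlas)
  regional <- extract_regional_means(pons, atlas,
                                     model$cn_reference$region_id)
  scr <- screen_hypometabolism(regional, model$cn_reference)

  glob <- gm_profiles(images, atlas, scaling = "global")
  out <- data.frame(subject_id = rownames(images) %||%
                      as.character(seq_len(nrow(images))),
                    passes_screen = scr$passes_screen,
                    n_flagged = scr$n_flagged,
                    subtype = "no_hypometabolism",
                    stringsAsFactors = FALSE)
  for (s in model$subtypes) out[[paste0("dist_", s)]] <- NA_real_
  if (any(scr$passes_screen)) {
    asg <- classify_nearest_centroid(glob[scr$passes_screen, , drop = FALSE],
                                     model)
    out$subtype[scr$passes_screen] <- asg$subtype
    for (s in model$subtypes)
      out[[paste0("dist_", s)]][scr$passes_screen] <- asg[[paste0("dist_", s)]]
  }
  out
}

#' Subtype frequency summary
#'
#' @param labels character/factor vector of subtype assignments.
#' @return data frame with `subtype`, `n`, `pct` (percentage of total).
#' @export
subtype_frequencies <- function(labels) {
  tab <- table(labels)
  data.frame(subtype = names(tab), n = as.integer(tab),
             pct = 100 * as.integer(tab) / sum(tab), row.names = NULL)
}

#' Name recovered clusters after the planted templates
#'
#' Matches each cluster centroid to the disease template whose globally
#' scaled expected pattern it correlates with best (greedy one-to-one
#' matching over decreasing correlation). Used to attach subtype names to
#' an unlabelled clustering solution in simulation studies; on real data
#' the analyst names subtypes from the effect-size maps instead.
#'
#' @param model a `subtype_model` with unlabelled centroids.
#' @param templates template list from [default_templates()].
#' @param atlas a `label_atlas`.
#' @return the model with `subtypes` and centroid row names replaced.
#' @export
match_subtype_names <- function(model, templates, atlas) {
  gm_lab <- atlas$labels[atlas$gm_mask]
  disease <- templates[vapply(templates,
                              function(t) any(t$delta > 0.02), logical(1))]
  expected <- t(vapply(disease, function(t) {
    v <- (1 - t$delta[as.character(gm_lab)])
    v / mean(v)
  }, numeric(sum(atlas$gm_mask))))
  k <- nrow(model$centroids)
  cors <- stats::cor(t(model$centroids), t(expected))
  rownames(cors) <- rownames(model$centroids)
  colnames(cors) <- names(disease)
  nm <- rep(NA_character_, k)
  cc <- cors
  for (step in seq_len(min(k, length(disease)))) {
    ij <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    nm[ij[1]] <- colnames(cc)[ij[2]]
    cc[ij[1], ] <- -Inf; cc[, ij[2]] <- -Inf
  }
  nm[is.na(nm)] <- paste0("cluster_", which(is.na(nm)))
  rownames(model$centroids) <- nm
  model$subtypes <- nm
  model
}
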