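#' Generate a synthetic brain parcellation
#'
#' Builds a small 3-D label atlas that plays the role of an anatomical
#' parcellation for the synthetic pipeline: an ellipsoidal "grey matter"
#' volume partitioned into bilateral cortical screening areas plus dedicated
#' medial-temporal, frontal and posterior temporo-parietal pattern regions,
#' and a pons reference region kept disjoint from grey matter.
#'
#' The construction is fully deterministic: cortical areas are obtained by
#' recursive median bisection of voxel coordinates, so the same grid always
#' yields bit-identical labels.
#'
#' @param grid_dims integer vector of length 3, each entry >= 12.
#' @param n_cortical number of cortical screening areas (default 48, >= 4).
#' @param voxel_size_mm isotropic voxel edge length in millimetres.
#' @return An object of class `label_atlas`: a list with `labels` (3-D
#'   integer array, 0 = background), `regions` (data frame with `region_id`,
#'   `name`, `set`, `n_vox` and centroid columns `cx`, `cy`, `cz`),
#'   `gm_mask` (logical array, the union of all non-pons regions) and
#'   `voxel_size_mm`.
#' @export
generate_atlas <- function(grid_dims = c(18L, 22L, 18L), n_cortical = 48L,
                           voxel_size_mm = 4) {
  grid_dims <- as.integer(grid_dims)
  if (length(grid_dims) != 3L || any(grid_dims < 12L))
    stop("each grid dimension must be >= 12")
  if (n_cortical < 4L)
    stop("at least 4 cortical regions are required")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")

  nx <- grid_dims[1]; ny <- grid_dims[2]; nz <- grid_dims[3]
  ctr <- (grid_dims + 1) / 2
  ax <- grid_dims / 2 - 1
  idx <- as.matrix(expand.grid(x = seq_len(nx), y = seq_len(ny), z = seq_len(nz)))
  r2 <- ((idx[, 1] - ctr[1]) / ax[1])^2 + ((idx[, 2] - ctr[2]) / ax[2])^2 +
    ((idx[, 3] - ctr[3]) / ax[3])^2
  brain <- r2 <= 1

  labels <- array(0L, dim = grid_dims)

  # pons: 3x3x3 block at the bottom centre, outside grey matter by fiat
  px <- round(ctr[1]) + (-1:1); py <- round(ctr[2]) + (-1:1); pz <- 2:4
  pons_mask <- array(FALSE, grid_dims)
  pons_mask[px, py, pz] <- TRUE

  gm <- brain & !pons_mask
  gm_lin <- which(gm)
  co <- idx[gm_lin, , drop = FALSE]

  assign_set <- rep(NA_character_, length(gm_lin))
  # anterior (frontal) and posterior slabs along y, medial-temporal block
  ant <- co[, 2] >= ctr[2] + 0.28 * ny
  post <- co[, 2] <= ctr[2] - 0.28 * ny
  mtl <- !ant & !post &
    abs(co[, 1] - ctr[1]) <= nx / 5 &
    co[, 3] <= ctr[3] - 0.18 * nz &
    !pons_adjacent(co, px, py, pz)
  assign_set[ant] <- "frontal"
  assign_set[post] <- "posterior_temporo_parietal"
  assign_set[mtl & is.na(assign_set)] <- "medial_temporal"
  cort <- is.na(assign_set)

  if (sum(cort) < 16L * n_cortical)
    stop("grid too small: cannot allot at least 8 voxels to each of ",
         n_cortical, " cortical regions (sizing error)")

  regions <- list()
  next_id <- 1L
  add_regions <- function(vox_lin, coords, set, k, prefix) {
    parts <- bisect_partition(coords, k)
    for (j in seq_len(k)) {
      sel <- vox_lin[parts == j]
      if (length(sel) < 8L)
        stop("region sizing failed for set '", set, "' (sizing error)")
      labels[sel] <<- next_id
      cen <- colMeans(idx[sel, , drop = FALSE])
      side <- if (cen[1] < ctr[1]) "L" else "R"
      regions[[length(regions) + 1L]] <<- data.frame(
        region_id = next_id,
        name = sprintf("%s_%02d_%s", prefix, j, side),
        set = set, n_vox = length(sel),
        cx = cen[1], cy = cen[2], cz = cen[3])
      next_id <<- next_id + 1L
    }
  }

  add_regions(gm_lin[cort], co[cort, , drop = FALSE], "cortical",
              as.integer(n_cortical), "cortical")
  add_regions(gm_lin[assign_set %in% "medial_temporal"],
              co[assign_set %in% "medial_temporal", , drop = FALSE],
              "medial_temporal", 2L, "medial_temporal")
  add_regions(gm_lin[assign_set %in% "frontal"],
              co[assign_set %in% "frontal", , drop = FALSE],
              "frontal", 2L, "frontal")
  add_regions(gm_lin[assign_set %in% "posterior_temporo_parietal"],
              co[assign_set %in% "posterior_temporo_parietal", , drop = FALSE],
              "posterior_temporo_parietal", 2L, "post_temporo_parietal")

  # pons last
  pons_lin <- which(pons_mask)
  labels[pons_lin] <- next_id
  cen <- colMeans(idx[pons_lin, , drop = FALSE])
  regions[[length(regions) + 1L]] <- data.frame(
    region_id = next_id, name = "pons", set = "pons",
    n_vox = length(pons_lin), cx = cen[1], cy = cen[2], cz = cen[3])

  regions <- do.call(rbind, regions)
  rownames(regions) <- NULL
  gm_mask <- array(FALSE, grid_dims)
  gm_mask[gm_lin] <- TRUE

  out <- list(labels = labels, regions = regions, gm_mask = gm_mask,
              voxel_size_mm = voxel_size_mm, dims = grid_dims)
  class(out) <- "label_atlas"
  validate_atlas(out)
  out
}

# voxels sharing a face/edge with the pons block are excluded from the
# medial-temporal set so that smoothing bleed stays symmetric
pons_adjacent <- function(co, px, py, pz) {
  co[, 1] >= min(px) - 1 & co[, 1] <= max(px) + 1 &
    co[, 2] >= min(py) - 1 & co[, 2] <= max(py) + 1 &
    co[, 3] >= min(pz) - 1 & co[, 3] <= max(pz) + 1
}

# deterministic recursive median bisection into k near-equal parts
bisect_partition <- function(coords, k) {
  n <- nrow(coords)
  part <- integer(n)
  rec <- function(rows, k, base) {
    if (k == 1L) { part[rows] <<- base; return(invisible()) }
    k1 <- k %/% 2L; k2 <- k - k1
    sub <- coords[rows, , drop = FALSE]
    ax <- which.max(apply(sub, 2, function(v) diff(range(v))))
    ord <- order(sub[, ax], sub[, 1], sub[, 2], sub[, 3])
    n1 <- round(length(rows) * k1 / k)
    rec(rows[ord[seq_len(n1)]], k1, base)
    rec(rows[ord[-seq_len(n1)]], k2, base + k1)
  }
  rec(seq_len(n), as.integer(k), 1L)
  part
}

validate_atlas <- function(atlas) {
  reg <- atlas$regions
  ids <- sort(reg$region_id)
  if (!identical(ids, seq_len(nrow(reg)))) stop("region ids must be contiguous from 1")
  pons_id <- reg$region_id[reg$set == "pons"]
  if (any(atlas$gm_mask & array(atlas$labels %in% pons_id, dim(atlas$labels))))
    stop("pons must be disjoint from the grey matter mask")
  non_pons <- array(atlas$labels > 0 & !(atlas$labels %in% pons_id),
                    dim(atlas$labels))
  if (!identical(as.vector(non_pons), as.vector(atlas$gm_mask)))
    stop("gm_mask must equal the union of non-pons regions")
  if (any(reg$n_vox[reg$set == "cortical"] < 8L))
    stop("every cortical region needs >= 8 voxels")
  for (s in c("cortical", "medial_temporal", "frontal",
              "posterior_temporo_parietal", "pons"))
    if (!any(reg$set == s)) stop("missing region set: ", s)
  invisible(atlas)
}

#' @export
print.label_atlas <- function(x, ...) {
  cat("label_atlas:", paste(x$dims, collapse = " x "), "voxels at",
      x$voxel_size_mm, "mm\n")
  cat("  regions:", nrow(x$regions), "(",
      sum(x$regions$set == "cortical"), "cortical )\n")
  cat("  grey matter voxels:", sum(x$gm_mask), "\n")
  invisible(x)
}

#' Region ids belonging to a named set
#'
#' @param atlas a `label_atlas`.
#' @param set one of `"cortical"`, `"medial_temporal"`, `"frontal"`,
#'   `"posterior_temporo_parietal"`, `"pons"`.
#' @return integer vector of region ids.
#' @export
regions_in_set <- function(atlas, set) {
  set <- match.arg(set, unique(atlas$regions$set))
  atlas$regions$region_id[atlas$regions$set == set]
}

#' Default hypometabolism subtype templates
#'
#' Returns the four regional reduction templates the simulator plants: a
#' typical pattern with deep posterior temporo-parietal involvement, a
#' limbic-predominant pattern with strong medial-temporal reduction
#' extending to mid-temporal and frontal cortex, a cortical-predominant
#' pattern with frontal and anterior cortical involvement but spared
#' medial temporal lobe, and a flat no-hypometabolism template.
#' Reductions are fractional uptake losses per region; subject-level
#' severity multiplies them.
#'
#' The supports of the three disease templates are kept largely disjoint
#' (each pattern occupies its own anterior-posterior tertile of the
#' cortical screening areas plus its defining pattern regions). This makes
#' the centered, globally scaled patterns close to mutually orthogonal —
#' planting subtype structure that severity scaling stretches along
#' separate directions rather than a shared hypometabolism axis.
#'
#' @param atlas a `label_atlas`.
#' @return named list of `subtype_template` objects, each a list with
#'   `name` and `delta` (named vector over all region ids).
#' @export
default_templates <- function(atlas) {
  reg <- atlas$regions
  ids <- reg$region_id
  cort <- reg[reg$set == "cortical", ]
  q <- stats::quantile(cort$cy, c(1 / 3, 2 / 3))
  cort_post <- cort$region_id[cort$cy <= q[1]]
  cort_mid <- cort$region_id[cort$cy > q[1] & cort$cy <= q[2]]
  cort_ant <- cort$region_id[cort$cy > q[2]]
  mtl <- ids[reg$set == "medial_temporal"]
  fro <- ids[reg$set == "frontal"]
  ptp <- ids[reg$set == "posterior_temporo_parietal"]

  blank <- stats::setNames(rep(0, length(ids)), ids)
  mk <- function(name, ...) {
    d <- blank
    vals <- list(...)
    for (nm in names(vals)) d[as.character(vals[[nm]]$ids)] <- vals[[nm]]$delta
    structure(list(name = name, delta = d), class = "subtype_template")
  }
  tpl <- list(
    typical = mk("typical",
      a = list(ids = ptp, delta = 0.30),
      b = list(ids = cort_post, delta = 0.22),
      c = list(ids = mtl, delta = 0.06)),
    limbic_predominant = mk("limbic_predominant",
      a = list(ids = mtl, delta = 0.32),
      b = list(ids = cort_mid, delta = 0.14),
      c = list(ids = fro, delta = 0.10)),
    cortical_predominant = mk("cortical_predominant",
      a = list(ids = fro, delta = 0.30),
      b = list(ids = cort_ant, delta = 0.24),
      c = list(ids = ptp, delta = 0.06)),
    no_hypometabolism = mk("no_hypometabolism"))
  validate_templates(tpl)
  tpl
}

validate_templates <- function(templates) {
  for (t in templates) {
    if (any(t$delta < 0 | t$delta > 0.5))
      stop("template deltas must lie in [0, 0.5]")
    if (t$name == "no_hypometabolism" && any(t$delta > 0.02))
      stop("no_hypometabolism template must have deltas <= 0.02")
  }
  disease <- templates[setdiff(names(templates), "no_hypometabolism")]
  if (length(disease) > 1) {
    for (i in seq_along(disease)) for (j in seq_along(disease)) {
      if (i < j &&
          max(abs(disease[[i]]$delta - disease[[j]]$delta)) < 0.05)
        stop("disease templates must differ by at least 0.05 somewhere")
    }
  }
  invisible(templates)
}
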