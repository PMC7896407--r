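#' Ward agglomerative clustering of voxel profiles
#'
#' Greedy agglomerative merging that at every step joins the pair of
#' clusters whose union minimally increases the total within-cluster sum of
#' squared Euclidean distances. The stored merge cost is the increase
#' itself, \deqn{\Delta SSE(A,B) = \frac{n_A n_B}{n_A + n_B}
#' \lVert c_A - c_B \rVert^2,} updated through the Lance-Williams
#' recurrence. Ties are broken deterministically by the smallest
#' `(min leaf id, max leaf id)` pair of the candidate clusters, so the tree
#' is reproducible. Ward's criterion is reducible, so merge costs are
#' non-decreasing; this is asserted on every tree.
#'
#' @param profiles subject x voxel numeric matrix (rows are clustered).
#'   Intended for globally scaled profiles so that the distance reflects the
#'   regional pattern, not overall severity.
#' @return object of class `linkage_tree`: `merges` data frame with columns
#'   `left`, `right` (node ids: leaves `1..n`, internal nodes `n+1..2n-1`),
#'   `cost` (Delta-SSE) and `size` of the merged cluster; plus `n_leaves`
#'   and `labels` (row names).
#' @export
ward_linkage <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (n < 2) stop("need at least 2 subjects")
  if (!all(is.finite(profiles))) stop("non-finite profile values (data error)")

  # initial Delta-SSE between singletons = squared distance / 2
  sq <- rowSums(profiles^2)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(profiles)
  D[D < 0] <- 0
  D <- D / 2
  diag(D) <- Inf

  size <- rep(1L, n)
  node <- seq_len(n)          # current tree-node id of each active cluster
  minleaf <- seq_len(n)       # smallest original leaf in each cluster
  active <- rep(TRUE, n)
  merges <- data.frame(left = integer(n - 1), right = integer(n - 1),
                       cost = numeric(n - 1), size = integer(n - 1))

  for (m in seq_len(n - 1)) {
    Dv <- D
    Dv[!active, ] <- Inf
    Dv[, !active] <- Inf
    cmin <- min(Dv)
    cand <- which(Dv <= cmin * (1 + 1e-12) & Dv <= cmin + 1e-300,
                  arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key1 <- pmin(minleaf[cand[, 1]], minleaf[cand[, 2]])
    key2 <- pmax(minleaf[cand[, 1]], minleaf[cand[, 2]])
    pick <- order(key1, key2)[1]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    if (minleaf[j] < minleaf[i]) { tmp <- i; i <- j; j <- tmp }

    merges$left[m] <- node[i]; merges$right[m] <- node[j]
    merges$cost[m] <- D[i, j]
    merges$size[m] <- size[i] + size[j]

    # Lance-Williams update for Ward's Delta-SSE cost
    others <- which(active); others <- others[others != i & others != j]
    if (length(others)) {
      ni <- size[i]; nj <- size[j]; nk <- size[others]
      newd <- ((ni + nk) * D[i, others] + (nj + nk) * D[j, others] -
                 nk * D[i, j]) / (ni + nj + nk)
      D[i, others] <- newd; D[others, i] <- newd
    }
    size[i] <- size[i] + size[j]
    node[i] <- n + m
    minleaf[i] <- min(minleaf[i], minleaf[j])
    active[j] <- FALSE
    D[j, ] <- Inf; D[, j] <- Inf
  }

  if (any(diff(merges$cost) < -1e-8 * max(abs(merges$cost))))
    stop("internal error: Ward merge costs decreased (reducibility violated)")

  out <- list(merges = merges, n_leaves = n,
              labels = rownames(profiles) %||% as.character(seq_len(n)))
  class(out) <- "linkage_tree"
  out
}

#' @export
print.linkage_tree <- function(x, ...) {
  cat("linkage_tree:", x$n_leaves, "leaves,", nrow(x$merges), "merges\n")
  cat("  final merge cost:", x$merges$cost[nrow(x$merges)], "\n")
  invisible(x)
}

#' Convert a linkage tree to an `hclust` object
#'
#' Heights can be reported either on the Delta-SSE cost scale or as
#' `sqrt(2 * cost)`, the scale used by `hclust(method = "ward.D2")`; the
#' mapping is monotone, so topology and cuts are identical.
#'
#' @param x a `linkage_tree`.
#' @param height `"delta_sse"` or `"ward_d2"`.
#' @param ... unused.
#' @return an object of class `hclust`.
#' @export
as.hclust.linkage_tree <- function(x, height = c("delta_sse", "ward_d2"),
                                   ...) {
  height <- match.arg(height)
  n <- x$n_leaves
  conv <- function(id) ifelse(id <= n, -id, id - n)
  merge <- cbind(conv(x$merges$left), conv(x$merges$right))
  h <- if (height == "ward_d2") sqrt(2 * x$merges$cost) else x$merges$cost
  hc <- list(merge = merge, height = h, order = hclust_order(merge, n),
             labels = x$labels, method = "ward", call = match.call(),
             dist.method = "euclidean")
  class(hc) <- "hclust"
  hc
}

hclust_order <- function(merge, n) {
  leaves <- function(row) {
    out <- integer(0)
    for (v in merge[row, ]) {
      out <- c(out, if (v < 0) -v else leaves(v))
    }
    out
  }
  leaves(n - 1L)
}

#' Cut a linkage tree into k clusters
#'
#' Undoes the last `k - 1` merges. Cluster labels are renumbered `1..k` by
#' decreasing cluster size, ties broken by the smallest member id.
#'
#' @param tree a `linkage_tree`.
#' @param k number of clusters, `1 <= k <= n_leaves`.
#' @return integer vector of cluster labels, one per leaf.
#' @export
cut_tree <- function(tree, k) {
  n <- tree$n_leaves
  if (k < 1 || k > n) stop("k out of range")
  parent <- seq_len(2L * n - 1L)
  find <- function(v) { while (parent[v] != v) v <- parent[v]; v }
  keep <- seq_len(n - k)
  for (m in keep) {
    a <- find(tree$merges$left[m]); b <- find(tree$merges$right[m])
    parent[a] <- n + m; parent[b] <- n + m
  }
  roots <- vapply(seq_len(n), find, integer(1))
  grp <- match(roots, unique(roots))
  sizes <- tabulate(grp)
  minmem <- vapply(seq_len(max(grp)), function(g) min(which(grp == g)),
                   integer(1))
  rank <- order(-sizes, minmem)
  relabel <- integer(length(rank)); relabel[rank] <- seq_along(rank)
  relabel[grp]
}

#' Davies-Bouldin index of a clustering
#'
#' \deqn{DB = \frac{1}{k} \sum_i \max_{j \ne i}
#'   \frac{S_i + S_j}{M_{ij}}} with \eqn{S_i} the mean Euclidean distance
#' of cluster members to their centroid and \eqn{M_{ij}} the distance
#' between centroids. Lower is better.
#'
#' @param profiles subject x voxel matrix.
#' @param labels cluster labels (k >= 2, all clusters non-empty).
#' @return scalar index.
#' @export
davies_bouldin <- function(profiles, labels) {
  profiles <- as.matrix(profiles)
  labels <- validate_labels(labels, nrow(profiles))
  k <- length(unique(labels))
  if (k < 2) stop("need at least 2 clusters")
  cent <- centroid_matrix(profiles, labels)
  S <- vapply(seq_len(k), function(g) {
    rows <- profiles[labels == g, , drop = FALSE]
    mean(sqrt(rowSums(sweep(rows, 2, cent[g, ])^2)))
  }, numeric(1))
  M <- as.matrix(stats::dist(cent))
  if (any(M[upper.tri(M)] == 0))
    stop("coincident centroids for distinct clusters (degenerate metric)")
  mean(vapply(seq_len(k), function(i) {
    max(((S[i] + S[-i]) / M[i, -i]))
  }, numeric(1)))
}

#' Mean silhouette width of a clustering
#'
#' Rousseeuw's silhouette: `s(i) = (b - a) / max(a, b)` where `a` is the
#' mean distance of `i` to its own cluster (excluding itself) and `b` the
#' smallest mean distance to another cluster. Members of singleton
#' clusters, and points with `a = b = 0`, score 0. Higher is better.
#'
#' @param profiles subject x voxel matrix.
#' @param labels cluster labels (k >= 2).
#' @param d optional precomputed full distance matrix for `profiles`.
#' @return list with `mean` and per-sample `widths`.
#' @export
silhouette_score <- function(profiles, labels, d = NULL) {
  profiles <- as.matrix(profiles)
  labels <- validate_labels(labels, nrow(profiles))
  if (length(unique(labels)) < 2) stop("need at least 2 clusters")
  if (is.null(d)) d <- as.matrix(stats::dist(profiles))
  n <- nrow(d)
  ks <- sort(unique(labels))
  sizes <- table(factor(labels, levels = ks))
  # mean distance of each point to each cluster
  agg <- vapply(ks, function(g) rowSums(d[, labels == g, drop = FALSE]),
                numeric(n))
  widths <- vapply(seq_len(n), function(i) {
    g <- match(labels[i], ks)
    ng <- sizes[g]
    if (ng == 1) return(0)
    a <- agg[i, g] / (ng - 1)
    b <- min(agg[i, -g] / sizes[-g])
    if (a == 0 && b == 0) return(0)
    (b - a) / max(a, b)
  }, numeric(1))
  list(mean = mean(widths), widths = widths)
}

validate_labels <- function(labels, n) {
  labels <- as.integer(factor(labels))
  if (length(labels) != n) stop("labels must match the number of rows")
  if (any(is.na(labels))) stop("labels must not contain NA")
  labels
}

centroid_matrix <- function(profiles, labels) {
  ks <- sort(unique(labels))
  m <- vapply(ks, function(g) colMeans(profiles[labels == g, , drop = FALSE]),
              numeric(ncol(profiles)))
  # vapply collapses to a plain vector for one-voxel profiles
  if (is.null(dim(m))) matrix(m, ncol = 1) else t(m)
}

#' Objective selection of the number of clusters
#'
#' Cuts the Ward dendrogram at every candidate `k` and evaluates both the
#' silhouette criterion (maximized) and the Davies-Bouldin criterion
#' (minimized). The silhouette-selected `k` is the primary recommendation;
#' the Davies-Bouldin choice is reported as secondary, and disagreement
#' between the two is flagged, never silently resolved.
#'
#' @param profiles subject x voxel matrix (globally scaled for the intended
#'   use).
#' @param k_range candidate cluster numbers, default `2:10`.
#' @param tree optionally a precomputed `linkage_tree` for these profiles.
#' @return object of class `cluster_solution`: `k` (selected), `labels`
#'   (cut at `k`), `k_silhouette`, `k_davies_bouldin`, `agreement`,
#'   `criteria` (per-k table) and the `tree`.
#' @export
select_k <- function(profiles, k_range = 2:10, tree = NULL) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  if (min(k_range) < 2 || max(k_range) > n - 1)
    stop("k_range must lie within [2, n - 1]")
  if (is.null(tree)) tree <- ward_linkage(profiles)
  dmat <- as.matrix(stats::dist(profiles))
  crit <- data.frame(k = as.integer(k_range), silhouette = NA_real_,
                     davies_bouldin = NA_real_)
  labs <- list()
  for (i in seq_along(k_range)) {
    lab <- cut_tree(tree, k_range[i])
    labs[[i]] <- lab
    crit$silhouette[i] <- silhouette_score(profiles, lab, d = dmat)$mean
    crit$davies_bouldin[i] <- davies_bouldin(profiles, lab)
  }
  k_sil <- crit$k[which.max(crit$silhouette)]
  k_db <- crit$k[which.min(crit$davies_bouldin)]
  agreement <- k_sil == k_db
  if (!agreement)
    message("cluster-number criteria disagree: silhouette -> k = ", k_sil,
            ", Davies-Bouldin -> k = ", k_db,
            "; reporting the silhouette choice as primary")
  out <- list(k = k_sil, labels = labs[[match(k_sil, k_range)]],
              k_silhouette = k_sil, k_davies_bouldin = k_db,
              agreement = agreement, criteria = crit, tree = tree)
  class(out) <- "cluster_solution"
  out
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat("cluster_solution: k =", x$k, "(silhouette);",
      "Davies-Bouldin ->", x$k_davies_bouldin, "\n")
  print(x$criteria, row.names = FALSE)
  invisible(x)
}

#' Subtype model: cluster centroids plus CN regional reference
#'
#' Computes the per-cluster voxel-wise mean of globally scaled profiles
#' (the subtype mean patterns used for nearest-centroid matching) and
#' stores the CN regional reference (mean, SD of pons-scaled regional
#' means) used by the hypometabolism screen. Subtype names are assigned by
#' the analyst (or by [match_subtype_names()]).
#'
#' @param profiles subject x voxel matrix of globally scaled profiles.
#' @param labels cluster labels.
#' @param cn_reference data frame `region_id`, `mean`, `sd` from
#'   [cn_regional_reference()] (optional, required for screening).
#' @param subtype_names optional character vector, one per cluster label in
#'   label order.
#' @return object of class `subtype_model` with `centroids` (subtype x
#'   voxel), `cn_reference` and `subtypes` (the fixed subtype order used
#'   for tie-breaking).
#' @export
compute_centroids <- function(profiles, labels, cn_reference = NULL,
                              subtype_names = NULL) {
  profiles <- as.matrix(profiles)
  labels <- validate_labels(labels, nrow(profiles))
  cent <- centroid_matrix(profiles, labels)
  ks <- sort(unique(labels))
  nm <- subtype_names %||% paste0("cluster_", ks)
  if (length(nm) != length(ks)) stop("one subtype name per cluster required")
  rownames(cent) <- nm
  if (identical(attr(profiles, "scaling"), "global") &&
      any(abs(rowMeans(cent) - 1) > 0.01))
    stop("centroid means deviate from 1 beyond tolerance")
  if (!is.null(cn_reference)) {
    stopifnot(all(c("region_id", "mean", "sd") %in% names(cn_reference)))
    if (any(cn_reference$sd <= 0)) stop("CN reference SDs must be positive")
  }
  out <- list(centroids = cent, cn_reference = cn_reference, subtypes = nm)
  class(out) <- "subtype_model"
  out
}

#' @export
print.subtype_model <- function(x, ...) {
  cat("subtype_model:", nrow(x$centroids), "subtypes x",
      ncol(x$centroids), "voxels\n")
  cat("  subtypes:", paste(x$subtypes, collapse = ", "), "\n")
  if (!is.null(x$cn_reference))
    cat("  CN reference over", nrow(x$cn_reference), "regions\n")
  invisible(x)
}
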