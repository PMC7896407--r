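# Shared fixtures and independent oracles, built in code at test time.

# small atlas cached per session (deterministic construction)
small_atlas <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_atlas(c(18L, 22L, 18L))
    cache
  }
})

# a hand-built miniature atlas: region 1 = two "cortical" voxels,
# region 2 = two pons voxels, everything else background
mini_atlas <- function(vals_cortical = c(1, 3), vals_pons = c(2, 2)) {
  labels <- array(0L, c(4, 4, 4))
  labels[1, 1, 1] <- 1L; labels[2, 1, 1] <- 1L
  labels[3, 3, 3] <- 2L; labels[4, 3, 3] <- 2L
  gm <- array(FALSE, c(4, 4, 4))
  gm[labels == 1L] <- TRUE
  atlas <- list(labels = labels,
                regions = data.frame(
                  region_id = 1:2, name = c("cortical_01_L", "pons"),
                  set = c("cortical", "pons"), n_vox = c(2L, 2L),
                  cx = c(1.5, 3.5), cy = c(1, 3), cz = c(1, 3)),
                gm_mask = gm, voxel_size_mm = 4, dims = c(4L, 4L, 4L))
  class(atlas) <- "label_atlas"
  vol <- array(0, c(4, 4, 4))
  vol[labels == 1L] <- vals_cortical
  vol[labels == 2L] <- vals_pons
  list(atlas = atlas, volume = vol)
}

# exhaustive Ward oracle: at every step recompute the exact SSE increase
# of every possible pair merge from scratch and take the minimum, with the
# same (min leaf, max leaf) tie rule
brute_ward <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  sse <- function(rows) {
    if (length(rows) == 1) return(0)
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(n))
  costs <- numeric(0)
  sequence <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      dc <- sse(c(clusters[[i]], clusters[[j]])) - sse(clusters[[i]]) -
        sse(clusters[[j]])
      key <- c(min(min(clusters[[i]]), min(clusters[[j]])),
               max(min(clusters[[i]]), min(clusters[[j]])))
      if (is.null(best) || dc < best$dc - 1e-12 ||
          (abs(dc - best$dc) <= 1e-12 &&
           (key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2])))) {
        best <- list(i = i, j = j, dc = dc, key = key)
      }
    }
    costs <- c(costs, best$dc)
    sequence[[length(sequence) + 1L]] <-
      sort(c(min(clusters[[best$i]]), min(clusters[[best$j]])))
    clusters[[best$i]] <- c(clusters[[best$i]], clusters[[best$j]])
    clusters[[best$j]] <- NULL
  }
  list(costs = costs, pairs = sequence)
}

# naive Davies-Bouldin, written independently of the package version
naive_db <- function(x, lab) {
  ks <- sort(unique(lab))
  cent <- lapply(ks, function(g) colMeans(x[lab == g, , drop = FALSE]))
  S <- sapply(seq_along(ks), function(g) {
    rows <- which(lab == ks[g])
    mean(sapply(rows, function(r) sqrt(sum((x[r, ] - cent[[g]])^2))))
  })
  k <- length(ks)
  total <- 0
  for (i in seq_len(k)) {
    best <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      M <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (S[i] + S[j]) / M)
    }
    total <- total + best
  }
  total / k
}

# partition agreement ignoring label names
same_partition <- function(a, b) {
  tab <- table(a, b)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# adjusted Rand index (small independent implementation)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
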