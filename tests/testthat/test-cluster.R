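test_that("Ward linkage reproduces hand-computed merge costs", {
  x <- matrix(c(0, 1, 10), ncol = 1)
  tr <- ward_linkage(x)
  expect_equal(tr$merges$cost, c(0.5, (2 / 3) * 9.5^2), tolerance = 1e-12)
  expect_equal(tr$merges$size, c(2L, 3L))
  expect_equal(cut_tree(tr, 2), c(1, 1, 2))

  twin <- matrix(c(2, 2), ncol = 1)
  expect_equal(ward_linkage(twin)$merges$cost, 0)
  expect_error(ward_linkage(matrix(c(1, NA), ncol = 1)), "data error")
})

test_that("greedy Lance-Williams merging matches the exhaustive oracle", {
  set.seed(77)
  for (r in 1:25) {
    n <- sample(3:8, 1)
    x <- matrix(stats::rnorm(n * sample(1:3, 1)), nrow = n)
    tr <- ward_linkage(x)
    bf <- brute_ward(x)
    expect_equal(tr$merges$cost, bf$costs, tolerance = 1e-10)
    # total-SSE conservation: merge costs sum to the SSE about the grand mean
    total_sse <- sum(sweep(x, 2, colMeans(x))^2)
    expect_equal(sum(tr$merges$cost), total_sse,
                 tolerance = 1e-8 * max(1, total_sse))
    # reducibility
    expect_true(all(diff(tr$merges$cost) >= -1e-10))
  }
})

test_that("the tree agrees with hclust ward.D2 up to the height convention", {
  set.seed(5)
  x <- matrix(stats::rnorm(40 * 6), 40)
  tr <- ward_linkage(x)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  expect_equal(sort(sqrt(2 * tr$merges$cost)), sort(hc$height),
               tolerance = 1e-8)
  for (k in c(2, 3, 5)) {
    expect_true(same_partition(cut_tree(tr, k), stats::cutree(hc, k)))
  }
  conv <- as.hclust(tr, height = "ward_d2")
  expect_s3_class(conv, "hclust")
  expect_equal(conv$height, sqrt(2 * tr$merges$cost))
})

test_that("clustering is invariant to per-subject rescaling before global scaling", {
  set.seed(8)
  x <- matrix(stats::runif(30 * 12, 0.5, 2), 30)
  f <- stats::runif(30, 0.2, 5)
  t1 <- ward_linkage(scale_global(x))
  t2 <- ward_linkage(scale_global(x * f))
  expect_equal(t1$merges, t2$merges, tolerance = 1e-10)
})

test_that("cut_tree renumbers clusters by size and respects bounds", {
  set.seed(3)
  x <- matrix(stats::rnorm(12 * 2), 12)
  tr <- ward_linkage(x)
  expect_equal(cut_tree(tr, 1), rep(1, 12))
  expect_equal(sort(cut_tree(tr, 12)), 1:12)
  lab <- cut_tree(tr, 3)
  sizes <- as.vector(table(lab))
  expect_true(all(diff(sizes) <= 0))
  expect_error(cut_tree(tr, 0), "out of range")
  expect_error(cut_tree(tr, 13), "out of range")
})

test_that("Davies-Bouldin matches hand computation and a naive oracle", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(x, lab), 0.01, tolerance = 1e-12)
  # clusters of exactly repeated points
  xr <- matrix(c(1, 1, 5, 5), ncol = 1)
  expect_equal(davies_bouldin(xr, lab), 0)
  # coincident centroids
  xc <- matrix(c(0, 2, 0, 2), ncol = 1)
  expect_error(davies_bouldin(xc, lab), "degenerate")
  set.seed(21)
  for (r in 1:10) {
    y <- matrix(stats::rnorm(24 * 3), 24)
    l <- sample(1:3, 24, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(davies_bouldin(y, l), naive_db(y, l), tolerance = 1e-12)
  }
})

test_that("silhouette widths follow the Rousseeuw conventions", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  s <- silhouette_score(x, c(1, 1, 2, 2))
  expect_equal(s$widths[1], (10.05 - 0.1) / 10.05, tolerance = 1e-12)
  # singleton convention
  s3 <- silhouette_score(matrix(c(0, 1, 9), ncol = 1), c(1, 1, 2))
  expect_equal(s3$widths[3], 0)
  # all points identical
  sid <- silhouette_score(matrix(rep(2, 4), ncol = 1), c(1, 1, 2, 2))
  expect_equal(sid$widths, rep(0, 4))
  # oracle equivalence against cluster::silhouette
  set.seed(14)
  y <- matrix(stats::rnorm(30 * 4), 30)
  l <- sample(1:3, 30, replace = TRUE)
  ours <- silhouette_score(y, l)
  ref <- cluster::silhouette(l, stats::dist(y))
  expect_equal(ours$widths, unname(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("select_k reports both criteria and flags disagreement", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  # Davies-Bouldin rewards the singleton split here (S = 0), so the two
  # criteria disagree and the silhouette choice k = 2 is primary
  expect_message(sol <- select_k(x, 2:3), "disagree")
  expect_equal(sol$k, 2)
  expect_equal(sol$k_silhouette, 2)
  expect_false(sol$agreement)
  expect_equal(nrow(sol$criteria), 2)

  # two well-separated planted patterns -> both criteria say 2
  set.seed(31)
  blob <- rbind(matrix(stats::rnorm(40, 0, 0.3), 20),
                matrix(stats::rnorm(40, 6, 0.3), 20))
  sol2 <- select_k(blob, 2:6)
  expect_equal(sol2$k_silhouette, 2)
  expect_equal(sol2$k_davies_bouldin, 2)
  expect_error(select_k(blob, 2:40), "k_range")
})

test_that("centroids average cluster members and inherit global scaling", {
  x <- matrix(c(0, 2, 2, 0), 2, byrow = TRUE)
  m <- compute_centroids(x, c(1, 2))
  expect_equal(unname(m$centroids[1, ]), c(0, 2))
  m2 <- compute_centroids(x, c(1, 1))
  expect_equal(unname(m2$centroids[1, ]), c(1, 1))

  # noise-free cohort: centroid equals the globally scaled template image
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(n_cn = 0, n_ad = 12, n_mci = 0, seed = 4,
                       voxel_noise_sd = 0, region_effect_sd = 0,
                       pons_bias_sd = 0, global_factor_sd = 0,
                       severity_shape = Inf)
  sim <- generate_cross_sectional(atlas, tpl, cfg, groups = "AD")
  g <- gm_profiles(sim$images, atlas, "global")
  lab <- as.integer(factor(sim$cohort$true_subtype))
  cents <- compute_centroids(g, lab)
  gm_lab <- as.character(atlas$labels[atlas$gm_mask])
  for (st in unique(sim$cohort$true_subtype)) {
    v <- 1 - pmin(tpl[[st]]$delta[gm_lab], cfg$reduction_cap)
    v <- v / mean(v)
    row <- which(sort(unique(lab)) ==
                   lab[sim$cohort$true_subtype == st][1])
    expect_equal(unname(cents$centroids[row, ]), unname(v),
                 tolerance = 1e-10)
  }
})
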