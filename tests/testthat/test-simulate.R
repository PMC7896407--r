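test_that("largest-remainder rounding reproduces the planted study counts", {
  cfg <- cohort_config()
  expect_identical(
    largest_remainder(177, cfg$subtype_proportions_ad),
    c(limbic_predominant = 79L, typical = 86L, cortical_predominant = 12L))
  expect_identical(
    largest_remainder(217, cfg$subtype_proportions_mci),
    c(no_hypometabolism = 57L, limbic_predominant = 108L, typical = 49L,
      cortical_predominant = 3L))
  # property: counts never deviate from n * p by a full subject
  set.seed(42)
  for (r in 1:25) {
    p <- stats::runif(4); p <- p / sum(p)
    n <- sample(10:500, 1)
    cts <- largest_remainder(n, stats::setNames(p, letters[1:4]))
    expect_equal(sum(cts), n)
    expect_true(all(abs(cts - n * p) < 1))
  }
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(cohort_config(subtype_proportions_ad = c(a = 0.5, b = 0.6)),
               "sum to 1")
  expect_error(cohort_config(severity_mean_ad = 0.4,
                             severity_mean_mci = 0.5), "exceed")
  expect_error(cohort_config(voxel_noise_sd = -1), "SD")
  expect_error(cohort_config(hazard_ratios = c(no_hypometabolism = 0)),
               "positive")
})

test_that("the cross-sectional generator is seed-deterministic", {
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(n_cn = 6, n_ad = 9, n_mci = 8, seed = 11)
  s1 <- generate_cross_sectional(atlas, tpl, cfg)
  s2 <- generate_cross_sectional(atlas, tpl, cfg)
  expect_identical(s1$images, s2$images)
  expect_identical(s1$cohort, s2$cohort)
})

test_that("the generative equation is exactly invertible in the noise-free limit", {
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(n_cn = 2, n_ad = 6, n_mci = 0, seed = 5,
                       voxel_noise_sd = 0, region_effect_sd = 0,
                       pons_bias_sd = 0, global_factor_sd = 0,
                       severity_shape = Inf)
  sim <- generate_cross_sectional(atlas, tpl, cfg, groups = c("CN", "AD"))
  gm_lab <- atlas$labels[atlas$gm_mask]
  gm <- sim$images[, which(atlas$gm_mask), drop = FALSE]
  for (i in which(sim$cohort$group == "AD")) {
    st <- sim$cohort$true_subtype[i]
    s <- sim$manifest$drawn$severity[i]
    g <- sim$manifest$drawn$g[i]
    expected <- g * (1 - pmin(s * tpl[[st]]$delta[as.character(gm_lab)],
                              cfg$reduction_cap))
    expect_equal(unname(gm[i, ]), unname(expected), tolerance = 1e-12)
    # with fixed severity, same-subtype images are identical
    twin <- which(sim$cohort$true_subtype == st)
    expect_lt(max(abs(gm[twin[1], ] - gm[i, ])), 1e-12)
  }
})

test_that("planted medial-temporal contrast has the expected direction", {
  # limbic-predominant subjects show lower pons-scaled medial-temporal
  # uptake, and a higher lateral-to-medial temporal ratio, than typical
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  mtl <- regions_in_set(atlas, "medial_temporal")
  lateral <- regions_in_set(atlas, "cortical")
  hold_mtl <- hold_ratio <- logical(0)
  for (s in 1:20) {
    cfg <- cohort_config(n_ad = 100, n_cn = 0, n_mci = 0, seed = s,
                         subtype_proportions_ad = c(
                           limbic_predominant = 0.5, typical = 0.5,
                           cortical_predominant = 0))
    sim <- generate_cross_sectional(atlas, tpl, cfg, groups = "AD")
    pons <- scale_reference(sim$images, atlas)
    rm_mtl <- extract_regional_means(pons, atlas, mtl)
    lim <- sim$cohort$true_subtype == "limbic_predominant"
    hold_mtl <- c(hold_mtl, mean(rm_mtl[lim, ]) < mean(rm_mtl[!lim, ]))
    rm_all <- extract_regional_means(pons, atlas,
                                     c(mtl, lateral))
    ratios <- apply(rm_all, 1, regional_ratio, numerator = lateral,
                    denominator = mtl)
    hold_ratio <- c(hold_ratio, mean(ratios[lim]) > mean(ratios[!lim]))
  }
  expect_true(all(hold_mtl))
  expect_true(all(hold_ratio))
})

test_that("longitudinal scores reduce to the configured slopes without noise", {
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(n_cn = 0, n_ad = 0, n_mci = 12, seed = 2,
                       re_intercept_sd = 0, re_slope_sd = 0, resid_sd = 0)
  sim <- generate_cross_sectional(atlas, tpl, cfg, groups = "MCI")
  lng <- generate_longitudinal(sim$cohort, cfg)
  for (id in unique(lng$visits$subject_id)) {
    v <- lng$visits[lng$visits$subject_id == id, ]
    st <- sim$cohort$true_subtype[sim$cohort$subject_id == id]
    for (dom in c("MEM", "EF", "VS", "Lan")) {
      sl <- unname(stats::coef(stats::lm(v[[dom]] ~ v$month))[2])
      expect_equal(sl, unname(cfg$decline_slopes[dom, st]),
                   tolerance = 1e-10)
    }
  }
  # visit structure: month 0 present, strictly increasing months
  for (id in unique(lng$visits$subject_id)) {
    m <- lng$visits$month[lng$visits$subject_id == id]
    expect_equal(m[1], 0)
    expect_false(is.unsorted(m, strictly = TRUE))
  }
})

test_that("CDR trajectories encode the progression rule", {
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(n_cn = 0, n_ad = 0, n_mci = 30, seed = 9)
  sim <- generate_cross_sectional(atlas, tpl, cfg, groups = "MCI")
  lng <- generate_longitudinal(sim$cohort, cfg)
  for (id in sample(unique(lng$visits$subject_id), 10)) {
    v <- lng$visits[lng$visits$subject_id == id, ]
    ev <- lng$events[lng$events$subject_id == id, ]
    expect_true(all(v$cdr[v$month < ev$latent_time] == 0.5))
    expect_true(all(v$cdr[v$month >= ev$latent_time] >= 1))
  }
  # MCI subjects without a subtype are rejected
  bad <- sim$cohort
  bad$true_subtype[1] <- NA
  expect_error(generate_longitudinal(bad, cfg), "data error")
})

test_that("simulated event times recover the configured hazard ratios", {
  # large-n Cox fit on the latent continuous times
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(
    n_cn = 0, n_ad = 0, n_mci = 3000, seed = 7,
    subtype_proportions_mci = c(no_hypometabolism = 1 / 3,
                                limbic_predominant = 1 / 3,
                                typical = 1 / 3, cortical_predominant = 0))
  sim <- generate_cross_sectional(atlas, tpl, cfg, groups = "MCI",
                                  images = FALSE)
  lng <- generate_longitudinal(sim$cohort, cfg)
  fit <- cox_ph(lng$events, covariates = character(0))
  hr <- stats::setNames(fit$hr$hr, fit$hr$subtype)
  expect_equal(unname(hr["limbic_predominant"]), 4.82, tolerance = 0.15)
  expect_equal(unname(hr["typical"]), 5.99, tolerance = 0.15)
})
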