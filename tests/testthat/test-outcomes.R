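test_that("memory-executive discrepancy and volume ratio arithmetic", {
  expect_equal(adni_diff(-0.90, -1.11), 0.21)
  expect_equal(adni_diff(0.4, 0.4), 0)
  expect_equal(adni_diff(-1.31, -1.73), 0.42)
  expect_error(adni_diff(NA, 1), "finite")

  expect_equal(hv_ctv_ratio(4.05, 75.84), 1000 * 4.05 / 75.84)
  expect_equal(round(hv_ctv_ratio(4.05, 75.84), 1), 53.4)
  expect_equal(hv_ctv_ratio(2, 2), 1000)
  expect_equal(hv_ctv_ratio(8.1, 151.68), hv_ctv_ratio(4.05, 75.84))
  expect_error(hv_ctv_ratio(4, 0), "positive")
})

test_that("A/T/N thresholds pin the documented boundary behaviour", {
  expect_equal(atn_classify(av45_suvr = 1.11)$A, "+")
  expect_equal(atn_classify(av45_suvr = 1.10)$A, "-")
  expect_equal(atn_classify(csf_abeta = 880)$A, "-")   # strict below
  expect_equal(atn_classify(csf_abeta = 879.9)$A, "+")
  # AV45 takes precedence over CSF when both are present
  expect_equal(atn_classify(av45_suvr = 1.2, csf_abeta = 1200)$A, "+")
  r <- atn_classify(av45_suvr = 1.3, csf_ptau = 19.2, csf_ttau = 242)
  expect_equal(r$T, "-")                               # strict above
  expect_equal(r$N, "-")
  r2 <- atn_classify(av45_suvr = 1.3, csf_ptau = 19.3, csf_ttau = 242.1)
  expect_equal(r2$T, "+")
  expect_equal(r2$N, "+")
  r3 <- atn_classify(av45_suvr = 1.3)
  expect_equal(r3$T, "unknown")
  expect_equal(r3$N, "unknown")
  expect_error(atn_classify(csf_ptau = 25), "classification error")
})

test_that("Benjamini-Hochberg adjustment matches the hand example and stays monotone", {
  expect_equal(fdr_bh(c(0.005, 0.01, 0.03, 0.04)),
               c(0.02, 0.02, 0.04, 0.04))
  expect_equal(fdr_bh(0.3), 0.3)
  expect_equal(fdr_bh(rep(0.07, 5)), rep(0.07, 5))
  expect_error(fdr_bh(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (r in 1:10) {
    p <- stats::runif(20)
    q <- fdr_bh(p)
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q <= 1))
  }
})

test_that("continuous group tests reduce to classical forms and gate post hocs", {
  set.seed(9)
  y <- c(stats::rnorm(15, 0), stats::rnorm(15, 2))
  g <- rep(c("a", "b"), each = 15)
  res <- group_test_continuous(y, g)
  tt <- stats::t.test(y ~ g, var.equal = TRUE)
  expect_equal(res$f, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$global_p, tt$p.value, tolerance = 1e-10)

  # planted 1-SD shift is detected with high power
  rej <- replicate(20, {
    yy <- c(stats::rnorm(50, 0, 1), stats::rnorm(50, 1, 1))
    group_test_continuous(yy, rep(c("a", "b"), each = 50))$global_p < 0.05
  })
  expect_gte(mean(rej), 0.99)

  # no pairwise table under a null global test
  ynull <- stats::rnorm(60)
  gnull <- rep(c("a", "b", "c"), 20)
  resn <- group_test_continuous(ynull, gnull, alpha = 1e-6)
  expect_null(resn$pairwise)

  # covariates: collinearity is reported
  expect_error(
    group_test_continuous(y, g,
                          covariates = data.frame(x = as.numeric(g == "a"))),
    "rank-deficient")

  # with covariates and a real effect, pairwise p-values are BH-adjusted
  y3 <- c(stats::rnorm(20, 0), stats::rnorm(20, 1.5), stats::rnorm(20, 3))
  g3 <- rep(c("a", "b", "c"), each = 20)
  cov3 <- data.frame(age = stats::rnorm(60, 70, 5))
  res3 <- group_test_continuous(y3, g3, covariates = cov3)
  expect_equal(nrow(res3$pairwise), 3)
  expect_equal(res3$pairwise$p_adj, fdr_bh(res3$pairwise$p_raw))
})

test_that("categorical tests match the textbook chi-square computation", {
  even <- rbind(c(10, 10), c(10, 10))
  r <- group_test_categorical(even)
  expect_equal(r$chisq, 0)
  expect_equal(r$global_p, 1)

  skew <- rbind(c(30, 10), c(10, 30))
  expect_equal(group_test_categorical(skew)$chisq, 20)

  expect_error(group_test_categorical(rbind(c(1, 0), c(2, 0))), "empty")
  tri <- rbind(c(30, 10, 20), c(10, 30, 20))
  r3 <- group_test_categorical(tri)
  expect_equal(nrow(r3$pairwise), 3)
})

test_that("progression events follow the CDR 0.5 to >= 1 rule", {
  expect_equal(progression_event(c(0, 12, 24), c(0.5, 0.5, 1.0)),
               list(time = 24, event = TRUE))
  expect_equal(progression_event(c(0, 12), c(0.5, 0.5)),
               list(time = 12, event = FALSE))
  expect_equal(progression_event(c(0, 6), c(0.5, 2.0)),
               list(time = 6, event = TRUE))
  expect_error(progression_event(c(0, 6), c(0, 0.5)), "eligibility")
  expect_error(progression_event(c(0), c(0.5)), "follow-up")

  visits <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                       month = rep(c(0, 6, 12), 2),
                       cdr = c(0.5, 1, 1, 0.5, 0.5, 0.5))
  tab <- progression_table(visits)
  expect_equal(tab$time, c(6, 12))
  expect_equal(tab$event, c(TRUE, FALSE))
})

test_that("Kaplan-Meier estimates match the product-limit computation", {
  rec <- data.frame(time = c(1, 2, 3), event = c(TRUE, FALSE, TRUE))
  km <- kaplan_meier(rec, by = NULL)
  s <- summary(km, times = c(1, 3))
  expect_equal(s$surv, c(2 / 3, 0))

  none <- data.frame(time = 1:5, event = rep(FALSE, 5))
  expect_true(all(summary(kaplan_meier(none, by = NULL))$surv == 1))

  allev <- data.frame(time = c(2, 5, 9, 14), event = rep(TRUE, 4))
  sa <- summary(kaplan_meier(allev, by = NULL), times = c(2, 5, 9, 14))
  expect_equal(sa$surv, (4 - 1:4) / 4)
})

test_that("the Cox fit maximizes the hand-written partial likelihood", {
  rec <- data.frame(time = 1:4, event = TRUE,
                    subtype = c("x1", "x0", "x1", "x0"))
  fit <- cox_ph(rec, covariates = character(0), reference = "x0")
  neg_log_pl <- function(b) {
    -(log(exp(b) / (2 * exp(b) + 2)) + log(1 / (exp(b) + 2)) +
        log(exp(b) / (exp(b) + 1)))
  }
  opt <- stats::optimize(neg_log_pl, c(-5, 5))
  expect_equal(unname(stats::coef(fit$fit)), opt$minimum, tolerance = 1e-6)
})

test_that("Cox hazard ratios are invariant to covariate rescaling", {
  set.seed(15)
  n <- 300
  rec <- data.frame(
    time = stats::rexp(n, 0.05), event = stats::runif(n) < 0.6,
    subtype = sample(c("no_hypometabolism", "limbic_predominant"), n,
                     replace = TRUE),
    age = stats::rnorm(n, 72, 6))
  f1 <- cox_ph(rec, covariates = "age")
  rec2 <- rec; rec2$age <- rec2$age / 10
  f2 <- cox_ph(rec2, covariates = "age")
  expect_equal(f1$hr$hr, f2$hr$hr, tolerance = 1e-8)
  # no events in one group is an explicit error
  rec3 <- rec; rec3$event[rec3$subtype == "limbic_predominant"] <- FALSE
  expect_error(cox_ph(rec3, covariates = character(0)), "no events")
})

test_that("mixed-model trajectories recover planted slope differences", {
  atlas <- small_atlas()
  tpl <- default_templates(atlas)
  cfg <- cohort_config(n_cn = 0, n_ad = 0, n_mci = 150, seed = 30,
                       subtype_proportions_mci = c(
                         no_hypometabolism = 0.5, limbic_predominant = 0.5,
                         typical = 0, cortical_predominant = 0))
  ests <- sapply(1:4, function(r) {
    cfg_r <- cohort_config(n_cn = 0, n_ad = 0, n_mci = 150, seed = 30 + r,
                           subtype_proportions_mci = cfg$subtype_proportions_mci)
    sim_r <- generate_cross_sectional(atlas, tpl, cfg_r, groups = "MCI")
    lng <- generate_longitudinal(sim_r$cohort, cfg_r)
    st <- sim_r$cohort[, c("subject_id", "true_subtype", "age", "gender",
                           "education")]
    names(st)[2] <- "subtype"
    fit <- suppressMessages(lmm_trajectories(lng$visits, st, "MEM"))
    expect_equal(fit$method, "satterthwaite")
    fit$interactions$estimate
  })
  truth <- unname(cohort_config()$decline_slopes["MEM", "limbic_predominant"] -
                    cohort_config()$decline_slopes["MEM", "no_hypometabolism"])
  expect_equal(mean(ests), truth, tolerance = 0.2)
})

test_that("balanced complete data reduce the interaction to mean OLS slopes", {
  set.seed(44)
  n_per <- 30
  months <- seq(0, 36, 6)
  subj <- data.frame(
    subject_id = sprintf("P%03d", 1:(2 * n_per)),
    subtype = rep(c("no_hypometabolism", "typical"), each = n_per))
  slopes <- ifelse(subj$subtype == "typical", -0.012, -0.002) +
    stats::rnorm(2 * n_per, 0, 0.004)
  visits <- do.call(rbind, lapply(seq_len(nrow(subj)), function(i) {
    data.frame(subject_id = subj$subject_id[i], month = months,
               MEM = stats::rnorm(1, 0, 0.4) + slopes[i] * months +
                 stats::rnorm(length(months), 0, 0.1))
  }))
  fit <- suppressMessages(lmm_trajectories(visits, subj, "MEM",
                                           covariates = character(0)))
  ols <- sapply(seq_len(nrow(subj)), function(i) {
    v <- visits[visits$subject_id == subj$subject_id[i], ]
    unname(stats::coef(stats::lm(v$MEM ~ v$month))[2])
  })
  two_stage <- mean(ols[subj$subtype == "typical"]) -
    mean(ols[subj$subtype == "no_hypometabolism"])
  expect_equal(fit$interactions$estimate, two_stage, tolerance = 1e-6)
})

test_that("degenerate noise-free data fall back to exact least squares", {
  months <- seq(0, 24, 6)
  subj <- data.frame(subject_id = c("A", "B"),
                     subtype = c("no_hypometabolism", "typical"))
  visits <- rbind(
    data.frame(subject_id = "A", month = months, MEM = 1 - 0.002 * months),
    data.frame(subject_id = "B", month = months, MEM = 1 - 0.010 * months))
  fit <- suppressWarnings(suppressMessages(
    lmm_trajectories(visits, subj, "MEM", covariates = character(0))))
  expect_equal(fit$method, "lm")
  expect_equal(fit$interactions$estimate, -0.008, tolerance = 1e-10)
})
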