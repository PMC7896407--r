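#' Generate a synthetic cross-sectional FDG-PET cohort
#'
#' Draws subject-level images and baseline phenotypes under the generative
#' model
#' \deqn{x_{iv} = g_i \, b_{r(v)} \, (1 + \beta_{i r(v)}) \,
#'   (1 - \min(s_i \delta_{r(v)}, cap)) + \epsilon_{iv},}
#' where \eqn{g_i} is a log-normal global uptake factor, \eqn{s_i} a gamma
#' severity multiplier, \eqn{\delta} the subtype template of subject *i*,
#' \eqn{\beta} smooth regional biological variation, and \eqn{\epsilon}
#' i.i.d. voxel noise. Grey matter additionally carries a subject-level
#' relative bias against the pons reference signal (a cortex-to-brainstem
#' uptake coupling term), so that pons-scaled regional values share a
#' dominant subject-level component, as in real reference-region scaling;
#' global-mean scaling cancels the term exactly.
#' CN subjects use a zero template. Subtype counts follow the configured
#' proportions by largest-remainder rounding.
#'
#' @param atlas a `label_atlas`.
#' @param templates template list as from [default_templates()].
#' @param config a [cohort_config()].
#' @param groups which groups to generate (subset of CN/AD/MCI).
#' @param images generate voxel images (set `FALSE` for table-only cohorts,
#'   e.g. large survival simulations).
#' @return list of class `synthetic_cohort` with `images` (subject x voxel
#'   matrix over the full grid, row names = subject ids; `NULL` when
#'   `images = FALSE`), `cohort` (baseline table), `atlas`, and `manifest`
#'   (config echo plus every drawn subject-level parameter, template deltas
#'   and mode loadings).
#' @export
generate_cross_sectional <- function(atlas, templates, config,
                                     groups = c("CN", "AD", "MCI"),
                                     images = TRUE) {
  stopifnot(inherits(atlas, "label_atlas"), inherits(config, "cohort_config"))
  groups <- match.arg(groups, c("CN", "AD", "MCI"), several.ok = TRUE)
  validate_templates(templates)
  set.seed(config$seed)

  counts_ad <- largest_remainder(config$n_ad, config$subtype_proportions_ad)
  counts_mci <- largest_remainder(config$n_mci, config$subtype_proportions_mci)

  subj <- list()
  if ("CN" %in% groups && config$n_cn > 0)
    subj[["CN"]] <- data.frame(group = "CN",
                               subtype = rep(NA_character_, config$n_cn))
  if ("AD" %in% groups && config$n_ad > 0)
    subj[["AD"]] <- data.frame(group = "AD",
                               subtype = rep(names(counts_ad), counts_ad))
  if ("MCI" %in% groups && config$n_mci > 0)
    subj[["MCI"]] <- data.frame(group = "MCI",
                                subtype = rep(names(counts_mci), counts_mci))
  subj <- do.call(rbind, subj)
  n <- nrow(subj)
  subj$subject_id <- sprintf("%s%03d", substr(subj$group, 1, 1), seq_len(n))
  rownames(subj) <- NULL

  reg <- atlas$regions
  n_reg <- nrow(reg)
  pons_id <- reg$region_id[reg$set == "pons"]
  base <- ifelse(reg$set == "pons", 1.25, 1.0)

  # fixed smooth spatial modes from region centroids (pons excluded)
  modes <- scale(cbind(reg$cy, reg$cx, reg$cz))[, seq_len(config$n_region_modes),
                                                drop = FALSE]
  modes[reg$set == "pons", ] <- 0
  modes <- sweep(modes, 2, sqrt(colMeans(modes[reg$set != "pons", ,
                                               drop = FALSE]^2)), "/")

  # subject-level draws, in a fixed order
  g <- exp(stats::rnorm(n, 0, config$global_factor_sd))
  sev_mean <- ifelse(subj$group == "AD", config$severity_mean_ad,
                     config$severity_mean_mci)
  sev_draw <- if (is.infinite(config$severity_shape)) sev_mean else
    stats::rgamma(n, shape = config$severity_shape,
                  rate = config$severity_shape / sev_mean)
  severity <- ifelse(is.na(subj$subtype) | subj$subtype == "no_hypometabolism",
                     0, sev_draw)
  severity[subj$group == "CN"] <- 0
  eta <- stats::rnorm(n, 0, config$pons_bias_sd)
  W <- matrix(stats::rnorm(n * config$n_region_modes, 0,
                           config$region_effect_sd),
              n, config$n_region_modes)

  # per-subject regional multiplicative factor
  delta_mat <- matrix(0, n, n_reg)
  for (i in seq_len(n)) {
    if (!is.na(subj$subtype[i]))
      delta_mat[i, ] <- templates[[subj$subtype[i]]]$delta
  }
  red <- pmin(severity * delta_mat, config$reduction_cap)
  # grey matter carries the shared bias against the reference signal
  fac <- g * (1 + eta) * (1 + W %*% t(modes)) * (1 - red)
  fac <- sweep(fac, 2, base, "*")
  fac[, pons_id] <- g * base[pons_id]

  if (images) {
    lab_vec <- as.vector(atlas$labels)
    in_brain <- lab_vec > 0
    img <- matrix(0, n, length(lab_vec),
                  dimnames = list(subj$subject_id, NULL))
    img[, in_brain] <- fac[, lab_vec[in_brain]] +
      if (config$voxel_noise_sd > 0)
        stats::rnorm(n * sum(in_brain), 0, config$voxel_noise_sd) else 0
  } else img <- NULL

  cohort <- draw_baseline_phenotypes(subj)
  cohort$severity <- severity

  cfg_out <- unclass(config)
  ds <- cfg_out$decline_slopes
  cfg_out$decline_slopes <- stats::setNames(
    lapply(rownames(ds), function(r) as.list(ds[r, ])), rownames(ds))
  # named atomic vectors lose their names in JSON; store as objects
  for (f in c("subtype_proportions_ad", "subtype_proportions_mci",
              "hazard_ratios"))
    cfg_out[[f]] <- as.list(cfg_out[[f]])
  manifest <- list(
    config = cfg_out,
    counts_ad = as.list(counts_ad), counts_mci = as.list(counts_mci),
    drawn = data.frame(subject_id = subj$subject_id, group = subj$group,
                       true_subtype = subj$subtype, g = g,
                       severity = severity, pons_bias = eta),
    mode_loadings = unname(as.data.frame(modes)),
    template_deltas = lapply(templates, function(t) as.list(t$delta)),
    base_uptake = stats::setNames(as.list(base), reg$name))

  out <- list(images = img, cohort = cohort, atlas = atlas,
              manifest = manifest)
  class(out) <- "synthetic_cohort"
  out
}

draw_baseline_phenotypes <- function(subj) {
  par <- baseline_params()
  n <- nrow(subj)
  key <- ifelse(subj$group == "CN", "CN.none",
                paste(subj$group, subj$subtype, sep = "."))
  p <- par[key, ]
  rnormv <- function(m, s) stats::rnorm(n, m, s)
  mem <- rnormv(p$mem_m, p$mem_sd)
  ef <- rnormv(p$ef_m, p$ef_sd)
  tiv <- rnormv(1450, 120)
  hv <- pmax(rnormv(p$hv_m, p$hv_sd), 0.5)
  ctv <- pmax(rnormv(p$ctv_m, p$ctv_sd), hv + 1)
  wmh <- stats::rgamma(n, shape = (p$wmh_m / p$wmh_sd)^2,
                       rate = p$wmh_m / p$wmh_sd^2)
  data.frame(
    subject_id = subj$subject_id, group = subj$group,
    true_subtype = subj$subtype,
    age = round(rnormv(p$age_m, p$age_sd), 1),
    gender = factor(ifelse(stats::runif(n) < p$female, "F", "M"),
                    levels = c("F", "M")),
    education = pmax(6, round(rnormv(p$edu_m, p$edu_sd))),
    mmse = pmin(30L, pmax(0L, as.integer(round(rnormv(p$mmse_m, p$mmse_sd))))),
    MEM = mem, EF = ef,
    VS = rnormv(p$vs_m, p$vs_sd), Lan = rnormv(p$lan_m, p$lan_sd),
    DIFF = mem - ef,
    apoe4 = as.integer(stats::runif(n) < p$apoe4),
    av45_suvr = pmax(rnormv(p$av45_m, p$av45_sd), 0.7),
    csf_abeta = pmax(rnormv(p$abeta_m, p$abeta_sd), 150),
    csf_ttau = pmax(rnormv(p$ttau_m, p$ttau_sd), 50),
    csf_ptau = pmax(rnormv(p$ptau_m, p$ptau_sd), 5),
    hv = hv, ctv = ctv, tiv = tiv, wmh = wmh,
    wmh_method = factor(ifelse(stats::runif(n) < 0.5, "PD_T2", "FLAIR")))
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic_cohort:", nrow(x$cohort), "subjects (",
      paste(names(table(x$cohort$group)), table(x$cohort$group),
            collapse = ", "), ")\n")
  invisible(x)
}

#' Generate longitudinal visits and progression events for MCI subjects
#'
#' Domain scores follow a linear mixed model
#' `y = baseline + slope(subtype, domain) * month + u0 + u1 * month + noise`
#' with per-subject random intercepts and slopes. Time to dementia is drawn
#' from a proportional-hazards Weibull model (exponential by default) with
#' subtype-specific hazard ratios; the Clinical Dementia Rating is 0.5
#' before the event and 1 from the first visit at or after it, with
#' administrative censoring at each subject's last scheduled visit.
#'
#' @param cohort baseline table from [generate_cross_sectional()] (must
#'   contain MCI subjects with assigned subtypes).
#' @param config a [cohort_config()].
#' @param seed seed for the longitudinal draws (defaults to `config$seed + 1`).
#' @return list of class `longitudinal_data` with `visits` (subject_id,
#'   month, cdr, MEM, EF, VS, Lan) and `events` (subject_id, subtype,
#'   latent_time, time = observed continuous time, event, followup).
#' @export
generate_longitudinal <- function(cohort, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "cohort_config"))
  mci <- cohort[cohort$group == "MCI", , drop = FALSE]
  if (nrow(mci) == 0) stop("cohort contains no MCI subjects")
  if (any(is.na(mci$true_subtype)))
    stop("MCI subject without an assigned subtype (data error)")
  set.seed(as.integer(seed))

  n <- nrow(mci)
  iv <- config$visit_interval_months
  fu_grid <- seq(min(12L, config$followup_months), config$followup_months,
                 by = iv)
  followup <- sample(fu_grid, n, replace = TRUE)

  hr <- config$hazard_ratios[mci$true_subtype]
  if (any(is.na(hr))) stop("missing hazard ratio for a subtype")
  rate <- config$baseline_hazard * hr
  latent <- (-log(stats::runif(n)) / rate)^(1 / config$weibull_shape)

  u0 <- matrix(stats::rnorm(n * 4, 0, config$re_intercept_sd), n, 4)
  u1 <- matrix(stats::rnorm(n * 4, 0, config$re_slope_sd), n, 4)
  domains <- c("MEM", "EF", "VS", "Lan")

  visits <- vector("list", n)
  for (i in seq_len(n)) {
    months <- seq(0L, followup[i], by = iv)
    m <- length(months)
    slopes <- config$decline_slopes[domains, mci$true_subtype[i]]
    sc <- sapply(seq_along(domains), function(d) {
      as.numeric(mci[[domains[d]]][i]) + slopes[d] * months +
        u0[i, d] + u1[i, d] * months +
        stats::rnorm(m, 0, config$resid_sd)
    })
    sc <- matrix(sc, nrow = m,
                 dimnames = list(NULL, domains))
    visits[[i]] <- data.frame(subject_id = mci$subject_id[i], month = months,
                              cdr = ifelse(months >= latent[i], 1, 0.5), sc)
  }
  visits <- do.call(rbind, visits)
  rownames(visits) <- NULL

  events <- data.frame(
    subject_id = mci$subject_id, subtype = mci$true_subtype,
    latent_time = latent,
    time = pmin(latent, followup),
    event = latent <= followup,
    followup = followup)

  out <- list(visits = visits, events = events)
  class(out) <- "longitudinal_data"
  out
}
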