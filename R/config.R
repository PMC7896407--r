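#' Simulation configuration for a synthetic FDG-PET cohort
#'
#' Collects every tunable of the generative model with defaults that emulate
#' an amyloid-positive ADNI-like study: a cognitively normal (CN) reference
#' group, an AD-dementia group mixing three planted hypometabolism templates,
#' and a prodromal (MCI) group that includes a no-hypometabolism fraction.
#' Default mixture proportions are the planted counts 79/86/12 of 177 for
#' the dementia group and 57/108/49/3 of 217 for the prodromal group.
#'
#' @param n_cn,n_ad,n_mci group sizes.
#' @param subtype_proportions_ad,subtype_proportions_mci named simplex
#'   vectors over subtype names; must sum to 1 within 1e-9.
#' @param global_factor_sd log-scale SD of the subject-level global uptake
#'   factor (a nuisance the clustering must be invariant to).
#' @param severity_shape gamma shape of the subject severity multiplier
#'   (default 12, i.e. coefficient of variation about 0.29; smaller shapes
#'   give more within-subtype severity heterogeneity at the cost of
#'   cluster separability).
#' @param severity_mean_ad,severity_mean_mci group mean severities;
#'   dementia must exceed the prodromal mean.
#' @param voxel_noise_sd additive voxel noise SD (uptake units).
#' @param region_effect_sd SD of the loadings on the smooth regional
#'   variation modes (biological between-subject regional variability).
#' @param n_region_modes number of smooth spatial modes carrying the
#'   regional variability.
#' @param pons_bias_sd SD of the subject-level relative bias of grey-matter
#'   uptake against the pons reference signal (cortex-to-brainstem
#'   coupling); this is the dominant shared component of pons-scaled
#'   regional variation and cancels exactly under global-mean scaling.
#' @param reduction_cap upper bound on severity x template reduction.
#' @param hazard_ratios named map subtype -> hazard ratio of progression to
#'   dementia versus the no-hypometabolism reference.
#' @param baseline_hazard baseline hazard per month for the reference.
#' @param weibull_shape shape of the event-time distribution (1 =
#'   exponential, constant hazard).
#' @param decline_slopes domain x subtype matrix of mean cognitive decline
#'   in score units per month (rows MEM, EF, VS, Lan).
#' @param re_intercept_sd,re_slope_sd,resid_sd random-intercept, random-slope
#'   and residual SDs of the longitudinal score model.
#' @param followup_months,visit_interval_months visit schedule.
#' @param seed integer seed controlling all randomness.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cn = 179L, n_ad = 177L, n_mci = 217L,
                          subtype_proportions_ad = c(
                            limbic_predominant = 79, typical = 86,
                            cortical_predominant = 12) / 177,
                          subtype_proportions_mci = c(
                            no_hypometabolism = 57, limbic_predominant = 108,
                            typical = 49, cortical_predominant = 3) / 217,
                          global_factor_sd = 0.15,
                          severity_shape = 12,
                          severity_mean_ad = 1.0,
                          severity_mean_mci = 0.5,
                          voxel_noise_sd = 0.05,
                          region_effect_sd = 0.01,
                          n_region_modes = 3L,
                          pons_bias_sd = 0.06,
                          reduction_cap = 0.9,
                          hazard_ratios = c(
                            no_hypometabolism = 1, limbic_predominant = 4.82,
                            typical = 5.99, cortical_predominant = 5.99),
                          baseline_hazard = 0.003,
                          weibull_shape = 1,
                          decline_slopes = default_decline_slopes(),
                          re_intercept_sd = 0.4,
                          re_slope_sd = 0.004,
                          resid_sd = 0.15,
                          followup_months = 72L,
                          visit_interval_months = 6L,
                          seed = 1L) {
  cfg <- list(n_cn = as.integer(n_cn), n_ad = as.integer(n_ad),
              n_mci = as.integer(n_mci),
              subtype_proportions_ad = subtype_proportions_ad,
              subtype_proportions_mci = subtype_proportions_mci,
              global_factor_sd = global_factor_sd,
              severity_shape = severity_shape,
              severity_mean_ad = severity_mean_ad,
              severity_mean_mci = severity_mean_mci,
              voxel_noise_sd = voxel_noise_sd,
              region_effect_sd = region_effect_sd,
              n_region_modes = as.integer(n_region_modes),
              pons_bias_sd = pons_bias_sd,
              reduction_cap = reduction_cap,
              hazard_ratios = hazard_ratios,
              baseline_hazard = baseline_hazard,
              weibull_shape = weibull_shape,
              decline_slopes = decline_slopes,
              re_intercept_sd = re_intercept_sd,
              re_slope_sd = re_slope_sd,
              resid_sd = resid_sd,
              followup_months = as.integer(followup_months),
              visit_interval_months = as.integer(visit_interval_months),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

default_decline_slopes <- function() {
  m <- rbind(
    MEM = c(-0.002, -0.010, -0.010, -0.008),
    EF  = c(-0.002, -0.006, -0.011, -0.013),
    VS  = c(-0.001, -0.004, -0.007, -0.008),
    Lan = c(-0.002, -0.006, -0.007, -0.007))
  colnames(m) <- c("no_hypometabolism", "limbic_predominant", "typical",
                   "cortical_predominant")
  m
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_cn >= 0, cfg$n_ad >= 0, cfg$n_mci >= 0)
  for (p in list(cfg$subtype_proportions_ad, cfg$subtype_proportions_mci)) {
    if (is.null(names(p)) || any(p < 0))
      stop("subtype proportions must be named and non-negative")
    if (abs(sum(p) - 1) > 1e-9)
      stop("subtype proportions must sum to 1 (tolerance 1e-9)")
  }
  sds <- c(cfg$global_factor_sd, cfg$voxel_noise_sd, cfg$region_effect_sd,
           cfg$pons_bias_sd, cfg$re_intercept_sd, cfg$re_slope_sd,
           cfg$resid_sd)
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (!(cfg$severity_shape > 0)) stop("severity_shape must be positive")
  if (cfg$severity_mean_ad <= cfg$severity_mean_mci)
    stop("severity_mean_ad must exceed severity_mean_mci")
  if (cfg$severity_mean_ad <= 0 || cfg$severity_mean_mci <= 0)
    stop("severity means must be positive")
  if (cfg$baseline_hazard <= 0 || cfg$weibull_shape <= 0)
    stop("baseline hazard and Weibull shape must be positive")
  if (any(cfg$hazard_ratios <= 0)) stop("hazard ratios must be positive")
  if (cfg$followup_months < 1 || cfg$visit_interval_months < 1)
    stop("follow-up and visit interval must be positive integers")
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("cohort_config: CN", x$n_cn, "/ AD", x$n_ad, "/ MCI", x$n_mci,
      "(seed", paste0(x$seed, ")"), "\n")
  cat("  AD mixture: ",
      paste(sprintf("%s %.1f%%", names(x$subtype_proportions_ad),
                    100 * x$subtype_proportions_ad), collapse = ", "), "\n")
  cat("  MCI mixture:",
      paste(sprintf("%s %.1f%%", names(x$subtype_proportions_mci),
                    100 * x$subtype_proportions_mci), collapse = ", "), "\n")
  invisible(x)
}

#' Largest-remainder rounding of a mixture into integer counts
#'
#' Deterministically converts proportions into counts summing to `n`:
#' floors are taken first and remaining units go to the largest fractional
#' remainders (ties broken by position). Used so planted subtype counts
#' deviate from the configured proportions by less than one subject.
#'
#' @param n total count.
#' @param proportions named non-negative vector summing to 1.
#' @return named integer vector summing to `n`.
#' @export
largest_remainder <- function(n, proportions) {
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  raw <- n * proportions
  counts <- floor(raw)
  rem <- raw - counts
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(-rem, seq_along(rem))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(proportions))
}
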