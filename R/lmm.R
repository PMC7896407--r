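#' Mixed-effects model of domain-specific cognitive trajectories
#'
#' Fits `score ~ month * subtype + covariates` with per-subject random
#' intercepts and slopes. The subtype-by-time interaction coefficients
#' estimate differential decline relative to the reference subtype.
#' Inference uses Satterthwaite degrees of freedom; when the Satterthwaite
#' approximation is unavailable the function falls back to a normal
#' approximation, and for degenerate data (zero residual or random-effect
#' variance, where the mixed model is not estimable) to an ordinary linear
#' model — the `method` element records which path was used.
#'
#' @param visits data frame with `subject_id`, `month` and domain score
#'   columns.
#' @param subtypes data frame with `subject_id`, `subtype`, plus any
#'   covariate columns.
#' @param domain score column to model (e.g. `"MEM"`).
#' @param covariates covariate column names present in `subtypes`.
#' @param reference reference subtype level.
#' @return list with `fixed` (coefficient table), `interactions` (the
#'   `month:subtype` rows), `method` (`"satterthwaite"`, `"normal"` or
#'   `"lm"`), and the fitted model as `fit`.
#' @export
lmm_trajectories <- function(visits, subtypes, domain = "MEM",
                             covariates = c("age", "gender", "education"),
                             reference = "no_hypometabolism") {
  stopifnot(domain %in% names(visits))
  covariates <- intersect(covariates, names(subtypes))
  dat <- merge(visits[, c("subject_id", "month", domain)],
               subtypes[, c("subject_id", "subtype", covariates)],
               by = "subject_id")
  dat$subtype <- factor(dat$subtype)
  if (reference %in% levels(dat$subtype))
    dat$subtype <- stats::relevel(dat$subtype, ref = reference)
  names(dat)[names(dat) == domain] <- ".score"
  nvis <- table(dat$subject_id)
  if (mean(nvis >= 2) < 0.8)
    warning("fewer than 80% of subjects have at least 2 visits")

  rhs <- paste(c("month * subtype", covariates), collapse = " + ")
  fml <- stats::as.formula(paste(".score ~", rhs, "+ (1 + month | subject_id)"))

  fixed <- NULL; method <- NULL; fit <- NULL
  res <- try(suppressWarnings(suppressMessages(
    lmerTest::lmer(fml, data = dat))), silent = TRUE)
  if (!inherits(res, "try-error") &&
      stats::sigma(res) > 1e-8) {
    fit <- res
    ct <- try(stats::coef(summary(fit, ddf = "Satterthwaite")),
              silent = TRUE)
    if (!inherits(ct, "try-error") && all(is.finite(ct[, "df"]))) {
      fixed <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                          se = ct[, "Std. Error"], df = ct[, "df"],
                          t = ct[, "t value"], p = ct[, "Pr(>|t|)"])
      method <- "satterthwaite"
    } else {
      ct <- stats::coef(summary(fit))
      fixed <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                          se = ct[, "Std. Error"], df = NA_real_,
                          t = ct[, "t value"],
                          p = 2 * stats::pnorm(-abs(ct[, "t value"])))
      method <- "normal"
    }
    if (lme4::isSingular(fit))
      message("singular random-effects covariance; estimates retained ",
              "(consider a random-intercept-only model)")
  } else {
    # degenerate variance structure: plain fixed-effects least squares
    fit <- stats::lm(stats::as.formula(paste(".score ~", rhs)), data = dat)
    ct <- summary(fit)$coefficients
    fixed <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                        se = ct[, "Std. Error"], df = stats::df.residual(fit),
                        t = ct[, "t value"], p = ct[, "Pr(>|t|)"])
    method <- "lm"
    message("mixed model not estimable for this data; ",
            "fell back to a fixed-effects linear model")
  }
  rownames(fixed) <- NULL
  inter <- fixed[grepl("^month:subtype", fixed$term), , drop = FALSE]
  list(fixed = fixed, interactions = inter, method = method, fit = fit)
}
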