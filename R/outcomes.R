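#' Memory-executive discrepancy score
#'
#' The difference between the memory and executive-function composites
#' (MEM - EF). Positive values indicate a more pronounced executive
#' impairment relative to the memory deficit, and vice versa.
#'
#' @param mem,ef composite scores (vectorized).
#' @return `mem - ef`.
#' @export
adni_diff <- function(mem, ef) {
  if (any(!is.finite(mem)) || any(!is.finite(ef)))
    stop("composite scores must be finite")
  mem - ef
}

#' Hippocampal-to-cortical volume ratio
#'
#' `1000 * hv / ctv` per subject; the factor 1000 puts the ratio on the
#' conventional reporting scale. Group summaries should average per-subject
#' ratios, not take the ratio of group means.
#'
#' @param hv hippocampal volume (TIV-scaled).
#' @param ctv cortical composite volume (TIV-scaled), must be positive.
#' @return per-subject ratio.
#' @export
hv_ctv_ratio <- function(hv, ctv) {
  if (any(ctv <= 0)) stop("ctv must be positive")
  1000 * hv / ctv
}

#' A/T/N biomarker classification
#'
#' Amyloid (A) positivity is defined by AV45 SUVR at or above 1.11;
#' when SUVR is unavailable, by CSF amyloid-beta strictly below 880 pg/ml.
#' Tau (T) positivity is CSF p-tau strictly above 19.2 pg/ml and
#' neurodegeneration (N) is CSF t-tau strictly above 242 pg/ml; a missing
#' input yields `"unknown"` for that axis. At least one amyloid input must
#' be present per subject.
#'
#' @param av45_suvr,csf_abeta,csf_ptau,csf_ttau biomarker values (`NA` =
#'   missing), vectorized.
#' @return data frame with character columns `A`, `T`, `N` taking values
#'   `"+"`, `"-"`, `"unknown"`.
#' @export
atn_classify <- function(av45_suvr = NA, csf_abeta = NA, csf_ptau = NA,
                         csf_ttau = NA) {
  n <- max(length(av45_suvr), length(csf_abeta), length(csf_ptau),
           length(csf_ttau))
  av45_suvr <- rep_len(av45_suvr, n); csf_abeta <- rep_len(csf_abeta, n)
  csf_ptau <- rep_len(csf_ptau, n); csf_ttau <- rep_len(csf_ttau, n)
  if (any(is.na(av45_suvr) & is.na(csf_abeta)))
    stop("at least one amyloid input required per subject ",
         "(classification error)")
  A <- ifelse(!is.na(av45_suvr),
              ifelse(av45_suvr >= 1.11, "+", "-"),
              ifelse(csf_abeta < 880, "+", "-"))
  Tt <- ifelse(is.na(csf_ptau), "unknown", ifelse(csf_ptau > 19.2, "+", "-"))
  N <- ifelse(is.na(csf_ttau), "unknown", ifelse(csf_ttau > 242, "+", "-"))
  data.frame(A = A, T = Tt, N = N)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; monotone non-decreasing in
#' raw-p rank and capped at 1.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
fdr_bh <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Covariate-adjusted group comparison of a continuous outcome
#'
#' Global F test on the group factor in a linear model with optional
#' covariates (plain one-way ANOVA when none), followed — only when the
#' global test is significant at `alpha` — by pairwise covariate-adjusted
#' t tests with Benjamini-Hochberg correction. Rows with missing values
#' are dropped listwise and the count is reported.
#'
#' @param values numeric outcome.
#' @param group grouping factor (>= 2 levels with n >= 2 each).
#' @param covariates optional data frame of covariates.
#' @param alpha gate for the post hoc tests (default 0.05).
#' @return list with `global_p`, `f`, `df`, `n_used`, `n_missing`, and
#'   `pairwise` (data frame `group1`, `group2`, `p_raw`, `p_adj`; `NULL`
#'   when the gate is not passed).
#' @export
group_test_continuous <- function(values, group, covariates = NULL,
                                  alpha = 0.05) {
  group <- factor(group)
  dat <- data.frame(.y = values, .g = group)
  if (!is.null(covariates)) dat <- cbind(dat, as.data.frame(covariates))
  keep <- stats::complete.cases(dat)
  n_missing <- sum(!keep)
  dat <- dat[keep, , drop = FALSE]
  dat$.g <- droplevels(dat$.g)
  if (nlevels(dat$.g) < 2) stop("need at least 2 groups")
  if (any(table(dat$.g) < 2)) stop("each group needs n >= 2")

  rhs <- if (ncol(dat) > 2)
    paste(setdiff(names(dat), c(".y", ".g")), collapse = " + ") else "1"
  fit0 <- stats::lm(stats::as.formula(paste(".y ~", rhs)), data = dat)
  fit1 <- stats::lm(stats::as.formula(paste(".y ~", rhs, "+ .g")), data = dat)
  if (any(is.na(stats::coef(fit1))))
    stop("rank-deficient design; offending column(s): ",
         paste(names(stats::coef(fit1))[is.na(stats::coef(fit1))],
               collapse = ", "))
  an <- stats::anova(fit0, fit1)
  global_p <- an$`Pr(>F)`[2]
  fstat <- an$F[2]

  pairwise <- NULL
  if (is.finite(global_p) && global_p < alpha) {
    lev <- levels(dat$.g)
    pairs <- utils::combn(lev, 2)
    p_raw <- apply(pairs, 2, function(pr) {
      sub <- dat[dat$.g %in% pr, , drop = FALSE]
      sub$.g <- droplevels(sub$.g)
      f <- stats::lm(stats::as.formula(paste(".y ~", rhs, "+ .g")),
                     data = sub)
      ct <- summary(f)$coefficients
      ct[grep("^\\.g", rownames(ct)), "Pr(>|t|)"]
    })
    pairwise <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                           p_raw = p_raw, p_adj = fdr_bh(p_raw))
  }
  list(global_p = global_p, f = fstat,
       df = c(an$Df[2], stats::df.residual(fit1)),
       n_used = nrow(dat), n_missing = n_missing, pairwise = pairwise)
}

#' Chi-square comparison of group compositions
#'
#' Pearson chi-square test (no continuity correction) on a 2 x k count
#' table, with post hoc pairwise 2 x 2 proportion comparisons (BH-adjusted)
#' when the global test is significant.
#'
#' @param counts 2 x k matrix of non-negative counts, all column sums > 0.
#' @param alpha gate for the post hoc tests.
#' @return list with `chisq`, `global_p`, `df` and `pairwise`.
#' @export
group_test_categorical <- function(counts, alpha = 0.05) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2) stop("counts must be a 2 x k table")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(colSums(counts) == 0)) stop("empty column in count table")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  pairwise <- NULL
  if (ncol(counts) > 2 && is.finite(ct$p.value) && ct$p.value < alpha) {
    pairs <- utils::combn(ncol(counts), 2)
    p_raw <- apply(pairs, 2, function(pr) {
      suppressWarnings(stats::chisq.test(counts[, pr],
                                         correct = FALSE))$p.value
    })
    cn <- colnames(counts) %||% as.character(seq_len(ncol(counts)))
    pairwise <- data.frame(group1 = cn[pairs[1, ]], group2 = cn[pairs[2, ]],
                           p_raw = p_raw, p_adj = fdr_bh(p_raw))
  }
  list(chisq = unname(ct$statistic), global_p = ct$p.value,
       df = unname(ct$parameter), pairwise = pairwise)
}
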