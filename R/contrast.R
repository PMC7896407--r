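#' Voxel-wise covariate-adjusted two-group contrast
#'
#' Per voxel, ordinary least squares of intensity on an intercept, a group
#' indicator (1 = group A) and optional covariates. The group t statistic
#' is converted voxel-wise to Cohen's d. The sign convention is negative =
#' group A lower than group B, so hypometabolism in A shows as negative d.
#' Intended for pons-scaled profiles, the standard scaling for contrasts
#' against a control group.
#'
#' @param profiles_a,profiles_b subject x voxel matrices over the same
#'   voxels (e.g. from [gm_profiles()] with pons scaling).
#' @param covariates optional data frame of covariates, rows ordered as
#'   `rbind(profiles_a, profiles_b)`; factors are expanded via
#'   `model.matrix`.
#' @return object of class `contrast_result`: `t_map`, `d_map`, `df`,
#'   `n1`, `n2`, `covariates`.
#' @export
voxelwise_group_contrast <- function(profiles_a, profiles_b,
                                     covariates = NULL) {
  a <- as.matrix(profiles_a); b <- as.matrix(profiles_b)
  if (ncol(a) != ncol(b)) stop("profile matrices must share voxels")
  n1 <- nrow(a); n2 <- nrow(b)
  y <- rbind(a, b)
  grp <- c(rep(1, n1), rep(0, n2))
  X <- cbind(`(Intercept)` = 1, group = grp)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n1 + n2)
      stop("covariates must have one row per subject")
    Xc <- stats::model.matrix(~ ., data = covariates)[, -1, drop = FALSE]
    X <- cbind(X, Xc)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  p <- ncol(X)
  df <- n1 + n2 - p
  if (df < 1) stop("not enough residual degrees of freedom")
  xtx_inv <- chol2inv(qr.R(qx))
  beta <- qr.coef(qx, y)
  res <- y - X %*% beta
  sigma2 <- colSums(res^2) / df
  se <- sqrt(xtx_inv[2, 2] * sigma2)
  tmap <- beta[2, ] / se
  out <- list(t_map = tmap, d_map = t_to_cohens_d(tmap, n1, n2), df = df,
              n1 = n1, n2 = n2,
              covariates = if (is.null(covariates)) character(0)
                           else names(covariates))
  class(out) <- "contrast_result"
  out
}

#' @export
print.contrast_result <- function(x, ...) {
  cat("contrast_result:", length(x$t_map), "voxels; n =", x$n1, "vs",
      x$n2, "; df =", x$df, "\n")
  cat("  d range: [", round(min(x$d_map), 3), ",", round(max(x$d_map), 3),
      "]\n")
  invisible(x)
}

#' Convert a two-sample t statistic into Cohen's d
#'
#' `d = t * sqrt(1/n1 + 1/n2)`, applied element-wise with the sign
#' preserved — the standard two-sample conversion.
#'
#' @param t t statistic (scalar or vector).
#' @param n1,n2 group sizes (>= 2).
#' @return Cohen's d on the same shape as `t`.
#' @export
t_to_cohens_d <- function(t, n1, n2) {
  if (n1 < 2 || n2 < 2) stop("group sizes must be at least 2")
  t * sqrt(1 / n1 + 1 / n2)
}
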