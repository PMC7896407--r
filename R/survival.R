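#' Progression event from a subject's CDR trajectory
#'
#' Progression to dementia is operationalized as the change in Clinical
#' Dementia Rating from 0.5 to >= 1: the event occurs at the first visit
#' month with CDR >= 1; otherwise the subject is censored at the last
#' visit month. Baseline CDR must be 0.5 and at least one follow-up visit
#' is required.
#'
#' @param months visit months, strictly increasing, starting at 0.
#' @param cdr CDR scores at those visits.
#' @return list with `time` (months) and `event` (logical).
#' @export
progression_event <- function(months, cdr) {
  if (length(months) != length(cdr)) stop("months and cdr must align")
  if (is.unsorted(months, strictly = TRUE)) stop("months must be increasing")
  if (months[1] != 0) stop("baseline visit (month 0) required")
  if (cdr[1] != 0.5) stop("baseline CDR must be 0.5 (eligibility error)")
  if (length(months) < 2) stop("at least one follow-up visit required")
  hit <- which(cdr >= 1)
  if (length(hit)) list(time = months[hit[1]], event = TRUE)
  else list(time = months[length(months)], event = FALSE)
}

#' Progression events for a visit table
#'
#' Applies [progression_event()] per subject.
#'
#' @param visits data frame with `subject_id`, `month`, `cdr`.
#' @return data frame with `subject_id`, `time`, `event`.
#' @export
progression_table <- function(visits) {
  ids <- unique(visits$subject_id)
  out <- lapply(ids, function(id) {
    v <- visits[visits$subject_id == id, , drop = FALSE]
    v <- v[order(v$month), , drop = FALSE]
    pe <- progression_event(v$month, v$cdr)
    data.frame(subject_id = id, time = pe$time, event = pe$event)
  })
  do.call(rbind, out)
}

#' Kaplan-Meier curves by subtype
#'
#' Product-limit estimate of the survival (non-progression) function per
#' group.
#'
#' @param records data frame with `time`, `event` and a grouping column.
#' @param by name of the grouping column (default `"subtype"`); `NULL` for
#'   a single pooled curve.
#' @return a `survival::survfit` object.
#' @export
kaplan_meier <- function(records, by = "subtype") {
  stopifnot(all(c("time", "event") %in% names(records)))
  if (any(records$time <= 0)) stop("times must be positive")
  f <- if (is.null(by)) survival::Surv(time, event) ~ 1 else
    stats::as.formula(paste("survival::Surv(time, event) ~", by))
  survival::survfit(f, data = records)
}

#' Cox proportional-hazards model of progression to dementia
#'
#' Partial-likelihood fit (Breslow tie handling by default; Efron
#' available) of progression on subtype with covariates, relative to a
#' reference subtype. Hazard ratios are `exp(coef)` with Wald confidence
#' intervals.
#'
#' @param records data frame with `time`, `event`, a `subtype` column and
#'   any covariate columns.
#' @param covariates character vector of covariate column names (default
#'   age, gender, education; only those present are used).
#' @param reference reference subtype level (default
#'   `"no_hypometabolism"`).
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `hr` (data frame `subtype`, `hr`, `lo`, `hi`, `p`)
#'   and the fitted `coxph` model as `fit`.
#' @export
cox_ph <- function(records, covariates = c("age", "gender", "education"),
                   reference = "no_hypometabolism",
                   ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event", "subtype") %in% names(records)))
  if (any(records$time <= 0)) stop("times must be positive")
  records$subtype <- factor(records$subtype)
  if (reference %in% levels(records$subtype))
    records$subtype <- stats::relevel(records$subtype, ref = reference)
  ev <- table(records$subtype[records$event])
  if (any(ev == 0))
    stop("no events in group(s): ",
         paste(names(ev)[ev == 0], collapse = ", "))
  covariates <- intersect(covariates, names(records))
  rhs <- paste(c("subtype", covariates), collapse = " + ")
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~", rhs)),
    data = records, ties = ties)
  co <- summary(fit)$coefficients
  ci <- summary(fit)$conf.int
  if (any(!is.finite(co[, "coef"])) || any(!is.finite(co[, "se(coef)"])) ||
      any(abs(co[, "coef"]) > 15))
    stop("Cox model failed to converge (possible complete separation); ",
         "largest |coef| = ", round(max(abs(co[, "coef"])), 2))
  rows <- grep("^subtype", rownames(co))
  hr <- data.frame(subtype = sub("^subtype", "", rownames(co)[rows]),
                   hr = ci[rows, "exp(coef)"],
                   lo = ci[rows, "lower .95"], hi = ci[rows, "upper .95"],
                   p = co[rows, "Pr(>|z|)"])
  rownames(hr) <- NULL
  list(hr = hr, reference = reference, fit = fit)
}
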