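#' Case-control cohort container
#'
#' @param y Binary outcome vector (1 = case).
#' @param covariates data.frame of covariates (no intercept column; one is
#'   added at fit time).
#' @return Object of class `case_control_cohort`.
#' @export
case_control_cohort <- function(y, covariates) {
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L))) stop("y must be binary 0/1", call. = FALSE)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(y)) stop("covariate rows must match y",
                                          call. = FALSE)
  structure(list(y = y, covariates = covariates),
            class = "case_control_cohort")
}

#' Survival cohort container
#'
#' @param time Positive follow-up times.
#' @param event Binary event indicator (1 = event).
#' @param covariates data.frame of covariates.
#' @return Object of class `survival_cohort`.
#' @export
survival_cohort <- function(time, event, covariates) {
  time <- as.numeric(time)
  event <- as.integer(event)
  if (any(time <= 0)) stop("time must be > 0", call. = FALSE)
  if (!all(event %in% c(0L, 1L))) stop("event must be binary 0/1",
                                       call. = FALSE)
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(time)) stop("covariate rows must match time",
                                             call. = FALSE)
  structure(list(time = time, event = event, covariates = covariates),
            class = "survival_cohort")
}

#' Standardize covariates for the two-stage models
#'
#' Continuous covariates (more than two distinct non-missing values) are
#' z-scored; binary covariates are left on their 0/1 coding.
#'
#' @param covariates data.frame.
#' @return data.frame of the same shape.
#' @export
standardize_covariates <- function(covariates) {
  covariates <- as.data.frame(covariates)
  for (nm in names(covariates)) {
    v <- covariates[[nm]]
    if (!is.numeric(v)) next
    u <- unique(v[!is.na(v)])
    if (length(u) > 2L) {
      s <- stats::sd(v, na.rm = TRUE)
      if (s > 0) covariates[[nm]] <- (v - mean(v, na.rm = TRUE)) / s
    }
  }
  covariates
}

assoc_row <- function(outcome, theta, se, measure, pvalue, n, n_events) {
  data.frame(outcome = outcome, theta = theta, se = se,
             effect_measure = measure, estimate = exp(theta),
             ci_lower = exp(theta - 1.96 * se),
             ci_upper = exp(theta + 1.96 * se),
             pvalue = pvalue, fdr = NA_real_,
             n = n, n_cases_or_events = n_events,
             stringsAsFactors = FALSE)
}

grs_values <- function(grs) {
  if (inherits(grs, "grs_vector")) grs$standardized else as.numeric(grs)
}

#' Logistic GRS association (two-stage model, binary outcome)
#'
#' Fits `logit P(y=1) = intercept + theta * GRS + alpha' X` by maximum
#' likelihood and reports the Wald test of `theta = 0` as an odds ratio
#' per standard deviation of the GRS. Continuous covariates are z-scored
#' before fitting.
#'
#' @param cohort A `case_control_cohort`.
#' @param grs A `grs_vector` or numeric vector (standardized GRS).
#' @param outcome Label for the result row.
#' @return One-row data.frame (`AssociationResult`).
#' @export
fit_logistic_grs <- function(cohort, grs, outcome = "outcome") {
  stopifnot(inherits(cohort, "case_control_cohort"))
  g <- grs_values(grs)
  if (length(g) != length(cohort$y)) stop("GRS length must match cohort",
                                          call. = FALSE)
  if (length(unique(cohort$y)) < 2L) {
    stop("y must contain both cases and controls", call. = FALSE)
  }
  df <- cbind(data.frame(.y = cohort$y, .grs = g),
              standardize_covariates(cohort$covariates))
  fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
  if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
  cf <- summary(fit)$coefficients
  if (cf[".grs", "Std. Error"] > 50) {
    stop("unstable logistic fit (possible separation)", call. = FALSE)
  }
  assoc_row(outcome, cf[".grs", "Estimate"], cf[".grs", "Std. Error"], "OR",
            cf[".grs", "Pr(>|z|)"], length(g), sum(cohort$y))
}

#' Cox proportional-hazards GRS association (two-stage model, survival)
#'
#' Fits `h(t | GRS, X) = h0(t) exp(theta * GRS + alpha' X)` by partial
#' likelihood (Efron ties) and reports the Wald test of `theta = 0` as a
#' hazard ratio per standard deviation of the GRS.
#'
#' @param cohort A `survival_cohort` with at least one event.
#' @inheritParams fit_logistic_grs
#' @return One-row data.frame (`AssociationResult`).
#' @export
fit_cox_grs <- function(cohort, grs, outcome = "outcome") {
  stopifnot(inherits(cohort, "survival_cohort"))
  g <- grs_values(grs)
  if (length(g) != length(cohort$time)) stop("GRS length must match cohort",
                                             call. = FALSE)
  if (sum(cohort$event) == 0L) stop("no events in cohort", call. = FALSE)
  df <- cbind(data.frame(.time = cohort$time, .event = cohort$event,
                         .grs = g),
              standardize_covariates(cohort$covariates))
  rhs <- setdiff(names(df), c(".time", ".event"))
  fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                 paste(rhs, collapse = " + ")))
  fit <- survival::coxph(fml, data = df, ties = "efron")
  cf <- summary(fit)$coefficients
  assoc_row(outcome, cf[".grs", "coef"], cf[".grs", "se(coef)"], "HR",
            cf[".grs", "Pr(>|z|)"], length(g), sum(cohort$event))
}

#' GRS-by-covariate interaction test
#'
#' Refits the two-stage model with a `GRS x covariate` product term and
#' reports the Wald test on the product coefficient.
#'
#' @param cohort A `case_control_cohort` or `survival_cohort`.
#' @param grs GRS values as in [fit_logistic_grs()].
#' @param covariate_name Name of a covariate in the cohort design.
#' @return One-row data.frame for the product term.
#' @export
test_interaction <- function(cohort, grs, covariate_name) {
  g <- grs_values(grs)
  X <- standardize_covariates(cohort$covariates)
  if (!covariate_name %in% names(X)) {
    stop(sprintf("covariate '%s' not found in cohort design", covariate_name),
         call. = FALSE)
  }
  v <- X[[covariate_name]]
  if (length(unique(v[!is.na(v)])) < 2L) {
    stop(sprintf("covariate '%s' is constant", covariate_name), call. = FALSE)
  }
  X$.grs <- g
  X$.inter <- g * v
  label <- paste0("GRS x ", covariate_name)
  if (inherits(cohort, "case_control_cohort")) {
    df <- cbind(data.frame(.y = cohort$y), X)
    fit <- stats::glm(.y ~ ., data = df, family = stats::binomial())
    if (!fit$converged) stop("logistic fit did not converge", call. = FALSE)
    cf <- summary(fit)$coefficients
    assoc_row(label, cf[".inter", "Estimate"], cf[".inter", "Std. Error"],
              "OR", cf[".inter", "Pr(>|z|)"], length(g), sum(cohort$y))
  } else if (inherits(cohort, "survival_cohort")) {
    df <- cbind(data.frame(.time = cohort$time, .event = cohort$event), X)
    rhs <- setdiff(names(df), c(".time", ".event"))
    fml <- stats::as.formula(paste("survival::Surv(.time, .event) ~",
                                   paste(rhs, collapse = " + ")))
    fit <- survival::coxph(fml, data = df, ties = "efron")
    cf <- summary(fit)$coefficients
    assoc_row(label, cf[".inter", "coef"], cf[".inter", "se(coef)"], "HR",
              cf[".inter", "Pr(>|z|)"], length(g), sum(cohort$event))
  } else {
    stop("cohort must be a case_control_cohort or survival_cohort",
         call. = FALSE)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Step-up adjusted values, same order as the input.
#' @export
adjust_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify an association as significant, suggestive or null
#'
#' Significant if FDR < 0.05; suggestive if the unadjusted p-value is
#' < 0.05 but FDR is not; otherwise null.
#'
#' @param p,fdr Unadjusted p-value(s) and BH-adjusted value(s),
#'   `fdr >= p` elementwise.
#' @param fdr_threshold,p_threshold Decision thresholds (defaults 0.05).
#' @return Character vector in `{"significant","suggestive","null"}`.
#' @export
classify_significance <- function(p, fdr, fdr_threshold = 0.05,
                                  p_threshold = 0.05) {
  if (any(p <= 0 | p > 1)) stop("p must lie in (0, 1]", call. = FALSE)
  if (any(fdr < p - 1e-12)) stop("fdr must be >= p", call. = FALSE)
  ifelse(fdr < fdr_threshold, "significant",
         ifelse(p < p_threshold, "suggestive", "null"))
}

#' Batch GRS association over multiple outcomes with shared controls
#'
#' Each outcome's cases are contrasted against the shared outcome-free
#' control pool; outcomes below the minimum case count are excluded (and
#' logged); FDR is computed across the fitted batch.
#'
#' @param pheno data.frame with one binary column per outcome plus
#'   covariate columns; rows are samples aligned with `grs`.
#' @param outcome_cols Names of the binary outcome columns.
#' @param covariate_cols Names of the covariate columns.
#' @param grs GRS values as in [fit_logistic_grs()].
#' @param min_cases Minimum case count per outcome (default 60).
#' @return data.frame of association rows with `fdr` and `classification`
#'   filled; excluded outcomes in `attr(result, "excluded")`.
#' @export
run_association_batch <- function(pheno, outcome_cols, covariate_cols, grs,
                                  min_cases = 60L) {
  if (length(outcome_cols) == 0L) stop("no outcomes supplied", call. = FALSE)
  missing <- setdiff(c(outcome_cols, covariate_cols), names(pheno))
  if (length(missing)) {
    stop("phenotype table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  g <- grs_values(grs)
  stopifnot(length(g) == nrow(pheno))
  control_pool <- rowSums(pheno[, outcome_cols, drop = FALSE]) == 0
  rows <- list()
  excluded <- list()
  for (oc in outcome_cols) {
    is_case <- pheno[[oc]] == 1
    n_cases <- sum(is_case)
    if (n_cases < min_cases) {
      excluded[[length(excluded) + 1L]] <- data.frame(
        outcome = oc, n_cases = n_cases,
        reason = sprintf("fewer than %d cases", min_cases),
        stringsAsFactors = FALSE)
      message(sprintf("excluding outcome '%s': %d cases < %d",
                      oc, n_cases, min_cases))
      next
    }
    use <- is_case | control_pool
    cohort <- case_control_cohort(
      as.integer(is_case[use]),
      pheno[use, covariate_cols, drop = FALSE])
    rows[[length(rows) + 1L]] <- fit_logistic_grs(cohort, g[use],
                                                  outcome = oc)
  }
  if (!length(rows)) stop("no outcomes met the case threshold",
                          call. = FALSE)
  res <- do.call(rbind, rows)
  res$fdr <- adjust_fdr(res$pvalue)
  res$classification <- classify_significance(res$pvalue, res$fdr)
  attr(res, "excluded") <- if (length(excluded)) do.call(rbind, excluded) else
    data.frame(outcome = character(), n_cases = integer(),
               reason = character())
  res
}
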