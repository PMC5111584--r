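#' Fit the patient-level logistic risk model on pre-treatment data only
#'
#' Maximum-likelihood logistic regression of death on the patient covariates,
#' restricted to patients admitted in periods up to and including the cut
#' period of the companion panel. The fitted model is later applied unchanged
#' to post-period patients.
#'
#' @param pt a patient table as produced by [generate_patients()] (columns
#'   `unit`, `period`, `died`, covariates).
#' @param ds the companion [panel_dataset()] supplying the period order and
#'   the cut.
#' @return an object of class `risk_model`: the fitted coefficients, the glm
#'   fit, log-likelihood and number of pre-period patients used.
#' @export
fit_risk_model <- function(pt, ds) {
  validate_panel(ds)
  bad <- setdiff(unique(pt$period), ds$periods)
  if (length(bad)) stop("patient periods absent from panel: ",
                        paste(bad, collapse = ", "))
  if (!all(unique(pt$unit) %in% ds$units))
    stop("patient units absent from panel")
  if (!all(pt$died %in% c(0, 1))) stop("`died` must be binary")
  pre <- pt[match(pt$period, ds$periods) <= ds$cut, , drop = FALSE]
  if (nrow(pre) == 0) stop("no pre-period patient rows to fit on")
  if (length(unique(pre$died)) < 2)
    stop("pre-period data need at least one death and one survival")
  covs <- setdiff(names(pt), c("unit", "period", "died"))
  # drop constant covariates (no information, would be aliased)
  keep <- covs[vapply(covs, function(v) stats::var(pre[[v]]) > 0, logical(1))]
  form <- if (length(keep))
    stats::reformulate(keep, response = "died") else died ~ 1
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = pre),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  mu <- stats::fitted(fit)
  if (sep || !fit$converged ||
      (length(keep) > 0 && any(mu > 1 - 1e-10 | mu < 1e-10)))
    stop("risk model shows (quasi-)separation or non-convergence; ",
         "reduce or coarsen the patient covariates")
  structure(list(coefficients = stats::coef(fit), fit = fit,
                 covariates = keep, dropped = setdiff(covs, keep),
                 loglik = as.numeric(stats::logLik(fit)), n = nrow(pre)),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat("risk_model: logistic regression on", x$n, "pre-period patients\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Risk-adjusted mortality by unit and period
#'
#' Applies a fitted risk model to every patient, aggregates observed and
#' predicted mortality to the unit-period cell by unweighted patient means,
#' and returns `100 * (observed rate - mean predicted risk)` in percentage
#' points. Cells with no patients are returned as `NA` (missing), to be
#' handled by the panel balance policy.
#'
#' @param pt a patient table.
#' @param model a `risk_model` from [fit_risk_model()].
#' @param ds the companion [panel_dataset()] defining the unit/period grid.
#' @return a units x periods numeric matrix of risk-adjusted mortality in
#'   percentage points.
#' @export
risk_adjust <- function(pt, model, ds) {
  stopifnot(inherits(model, "risk_model"))
  missing_cov <- setdiff(model$covariates, names(pt))
  if (length(missing_cov))
    stop("patient table lacks model covariate(s): ",
         paste(missing_cov, collapse = ", "))
  pred <- stats::predict(model$fit, newdata = pt, type = "response")
  cell <- interaction(factor(pt$unit, levels = ds$units),
                      factor(pt$period, levels = ds$periods), drop = FALSE)
  obs <- tapply(pt$died, cell, mean)
  exp_risk <- tapply(pred, cell, mean)
  out <- matrix(100 * (obs - exp_risk), nrow = length(ds$units),
                dimnames = list(ds$units, ds$periods))
  out
}
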