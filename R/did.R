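#' Two-way fixed-effects difference-in-differences estimator
#'
#' Estimates the model `Y_it = delta_t + mu_i + alpha D_it + e_it` by least
#' squares with unit and period dummies, where `D_it = 1` for treated units
#' after the cut period. The standard error is cluster-robust by unit
#' (sandwich estimator with the HC1-type finite-sample cluster correction);
#' p-values use a t distribution with (number of clusters - 1) degrees of
#' freedom. In the 2x2 case the point estimate equals the four-means DiD
#' formula.
#'
#' @param ds a [panel_dataset()].
#' @param weights optional regression weights: `"freq"` uses the panel's
#'   patient counts per unit-period (the ATT weighted for patient numbers); a
#'   named vector supplies one weight per unit; default unweighted.
#' @return an object of class `did_result`: `att`, `se_cluster`, `p_value`,
#'   `n_units`, `n_periods`, `df`, `residual_sd`, and the underlying `lm` fit.
#' @export
did_estimate <- function(ds, weights = NULL) {
  validate_panel(ds)
  if (length(ds$donor_units) == 0)
    stop("treatment indicator is collinear with unit or period effects: ",
         "no untreated units in the panel")
  long <- data.frame(
    unit = factor(rep(ds$units, times = length(ds$periods))),
    period = factor(rep(ds$periods, each = length(ds$units)),
                    levels = ds$periods),
    outcome = as.vector(ds$outcome),
    stringsAsFactors = FALSE
  )
  long$D <- as.numeric(long$unit %in% ds$treated_units &
                         as.integer(long$period) > ds$cut)
  wvec <- if (is.null(weights)) NULL
    else if (identical(weights, "freq")) as.vector(ds$freq)
    else weights[as.character(long$unit)]
  fit <- stats::lm(outcome ~ D + unit + period, data = long, weights = wvec)
  if (is.na(stats::coef(fit)["D"]))
    stop("treatment indicator is collinear with unit or period effects")
  # summary.lm warns on zero-residual fits inside sandwich::bread; that
  # degenerate case is legitimate here (noiseless panels) and already visible
  # through a zero cluster-robust SE.
  vc <- withCallingHandlers(
    sandwich::vcovCL(fit, cluster = long$unit, type = "HC1"),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  att <- unname(stats::coef(fit)["D"])
  se <- sqrt(vc["D", "D"])
  df <- length(ds$units) - 1
  p <- 2 * stats::pt(abs(att / se), df = df, lower.tail = FALSE)
  structure(list(att = att, se_cluster = se, p_value = p,
                 n_units = length(ds$units),
                 n_periods = length(ds$periods), df = df,
                 residual_sd = stats::sd(stats::residuals(fit)),
                 fit = fit),
            class = "did_result")
}

#' @export
print.did_result <- function(x, ...) {
  cat(sprintf(
    "did_result: ATT = %.4f (cluster-robust SE %.4f, p = %.4g, %d units x %d periods)\n",
    x$att, x$se_cluster, x$p_value, x$n_units, x$n_periods))
  invisible(x)
}

# Unit-level matching features: covariates plus pre-period outcomes,
# standardised by the pooled (treated + donor) standard deviation.
match_features <- function(ds, covariates = TRUE, pre_outcomes = TRUE) {
  feats <- NULL
  if (isTRUE(covariates) && ncol(ds$covariates) > 0)
    feats <- ds$covariates
  if (isTRUE(pre_outcomes)) {
    pre <- ds$outcome[, seq_len(ds$cut), drop = FALSE]
    colnames(pre) <- paste0("pre_", colnames(pre))
    feats <- cbind(feats, pre)
  }
  if (is.null(feats) || ncol(feats) == 0)
    stop("no matching features selected")
  sds <- apply(feats, 2, stats::sd)
  feats <- feats[, sds > .Machine$double.eps^0.5, drop = FALSE]
  scale(feats)
}

smd_table <- function(feats, treated, controls) {
  ft <- feats[treated, , drop = FALSE]
  fc <- feats[controls, , drop = FALSE]
  sp <- sqrt((apply(ft, 2, stats::var) + apply(fc, 2, stats::var)) / 2)
  smd <- (colMeans(ft) - colMeans(fc)) / ifelse(sp > 0, sp, 1)
  data.frame(feature = colnames(feats), smd = unname(smd))
}

#' Greedy 1:1 Mahalanobis matching of treated units to donors
#'
#' Matches each treated unit to its nearest unmatched donor (no replacement)
#' by Mahalanobis distance on standardised covariates and pre-period
#' outcomes, processing treated units in a seeded random order. A singular
#' feature covariance matrix triggers a logged fallback to diagonal variance
#' scaling. Returns the panel restricted to the treated units and their
#' matches, with a balance table of standardised mean differences before and
#' after matching.
#'
#' @param ds a [panel_dataset()].
#' @param covariates include unit covariates as matching features (default
#'   `TRUE`).
#' @param pre_outcomes include pre-period outcomes as features (default
#'   `TRUE`).
#' @param seed seed for the processing order of treated units.
#' @param order optional explicit processing order (character vector of
#'   treated unit ids), overriding the random order.
#' @return a `panel_dataset` containing treated units and matched donors,
#'   with attributes `matches` (data frame: treated, donor, distance) and
#'   `balance` (feature, smd_before, smd_after).
#' @export
match_units <- function(ds, covariates = TRUE, pre_outcomes = TRUE,
                        seed = 1L, order = NULL) {
  validate_panel(ds)
  if (length(ds$donor_units) < length(ds$treated_units))
    stop("need at least as many donors as treated units for 1:1 matching")
  feats <- match_features(ds, covariates, pre_outcomes)
  Sig <- stats::cov(feats)
  Sinv <- tryCatch(solve(Sig), error = function(e) NULL)
  if (is.null(Sinv)) {
    message("singular feature covariance; falling back to diagonal scaling")
    Sinv <- diag(1 / pmax(diag(Sig), .Machine$double.eps), ncol(Sig))
  }
  ord <- if (!is.null(order)) {
    stopifnot(setequal(order, ds$treated_units))
    order
  } else withr::with_seed(as.integer(seed), sample(ds$treated_units))

  pool <- ds$donor_units
  matches <- data.frame(treated = character(0), donor = character(0),
                        distance = numeric(0), stringsAsFactors = FALSE)
  for (u in ord) {
    dif <- sweep(feats[pool, , drop = FALSE], 2, feats[u, ])
    d2 <- rowSums((dif %*% Sinv) * dif)
    j <- which.min(d2)
    matches <- rbind(matches,
                     data.frame(treated = u, donor = pool[j],
                                distance = sqrt(max(d2[j], 0)),
                                stringsAsFactors = FALSE))
    pool <- pool[-j]
  }
  before <- smd_table(feats, ds$treated_units, ds$donor_units)
  after <- smd_table(feats, matches$treated, matches$donor)
  keep <- c(ds$treated_units, matches$donor)
  out <- reassign_treated(ds, ds$treated_units, keep_units = keep)
  out <- validate_panel(out)
  attr(out, "matches") <- matches
  attr(out, "balance") <- data.frame(feature = before$feature,
                                     smd_before = before$smd,
                                     smd_after = after$smd)
  out
}

#' Per-unit synthetic controls with frequency-weighted aggregation
#'
#' Fits one synthetic control per treated unit (donor pool: all donors),
#' aggregates the unit-level gaps to region level with the per-period patient
#' counts of the treated units, and computes the ATT exactly as the aggregate
#' estimator does.
#'
#' @param ds a [panel_dataset()].
#' @param predictors a [predictor_spec()].
#' @param control an [scm_control()].
#' @return an object of class `scm_per_unit`: `fits` (named list of per-unit
#'   `scm_fit`s; failed units dropped with a warning), `gaps` (region-level),
#'   `att`, `pre_rmspe` (of the aggregated gaps), `failed`.
#' @export
scm_per_unit <- function(ds, predictors = predictor_spec(),
                         control = scm_control()) {
  validate_panel(ds)
  fits <- list()
  failed <- character(0)
  for (u in ds$treated_units) {
    ds_u <- reassign_treated(ds, u, keep_units = c(u, ds$donor_units))
    fu <- tryCatch(fit_scm(ds_u, predictors, control), error = function(e) e)
    if (inherits(fu, "error")) {
      warning("per-unit fit failed for ", u, ": ", conditionMessage(fu))
      failed <- c(failed, u)
    } else fits[[u]] <- fu
  }
  if (!length(fits)) stop("all per-unit synthetic control fits failed")
  ok <- names(fits)
  f <- ds$freq[ok, , drop = FALSE]
  gap_mat <- do.call(rbind, lapply(fits, `[[`, "gaps"))
  gaps <- colSums(gap_mat * f) / colSums(f)
  T0 <- ds$cut
  post <- seq_along(gaps) > T0
  fw <- colSums(f)[post]
  if (control$att_weighting == "cumulative") fw <- cumsum(fw)
  att <- sum(gaps[post] * fw) / sum(fw)
  structure(list(fits = fits, gaps = stats::setNames(gaps, ds$periods),
                 att = att,
                 pre_rmspe = sqrt(mean(gaps[seq_len(T0)]^2)),
                 failed = failed, periods = ds$periods, cut = T0),
            class = "scm_per_unit")
}

#' Synthetic control plus DiD hybrid
#'
#' Builds a new panel containing each treated unit and its synthetic
#' counterpart (outcome series \eqn{\sum_j w_j^{(i)} Y_{jt}}, carrying the
#' treated unit's patient counts), then applies the two-way fixed-effects DiD
#' estimator to that panel. Inference is conditional on the estimated donor
#' weights: the reported uncertainty ignores the weight-estimation step, and
#' the result carries `conditional_on_weights = TRUE` to flag this.
#'
#' @param ds a [panel_dataset()].
#' @param per_unit an [scm_per_unit()] result for `ds`.
#' @return a `did_result` with the added field `conditional_on_weights`.
#' @export
scm_plus_did <- function(ds, per_unit) {
  stopifnot(inherits(per_unit, "scm_per_unit"))
  ok <- names(per_unit$fits)
  donorsY <- t(ds$outcome[ds$donor_units, , drop = FALSE])  # T x J
  synthY <- vapply(ok, function(u)
    as.numeric(donorsY %*% per_unit$fits[[u]]$w),
    numeric(length(ds$periods)))
  synth_ids <- paste0("synth_", ok)
  Y <- rbind(ds$outcome[ok, , drop = FALSE],
             matrix(t(synthY), nrow = length(ok), byrow = FALSE,
                    dimnames = list(synth_ids, ds$periods)))
  f <- rbind(ds$freq[ok, , drop = FALSE],
             matrix(ds$freq[ok, , drop = FALSE], nrow = length(ok),
                    dimnames = list(synth_ids, ds$periods)))
  region <- stats::setNames(c(ds$region_of[ok], rep("synthetic", length(ok))),
                            c(ok, synth_ids))
  ds2 <- panel_dataset(Y, f, treated_units = ok, region_of = region,
                       cut_period = ds$cut_period)
  res <- did_estimate(ds2)
  res$conditional_on_weights <- TRUE
  res
}

#' Leave-one-region-out sensitivity of the aggregate synthetic control
#'
#' Refits the full synthetic control once per donor region with that region's
#' units removed from the donor pool, reporting the ATT per deletion and the
#' spread. Deletions leaving fewer than two donors are skipped with a warning.
#'
#' @param ds a [panel_dataset()].
#' @param predictors a [predictor_spec()].
#' @param control an [scm_control()].
#' @return a data frame (class `loo_result`) with columns `region`, `att`,
#'   `pre_rmspe`, `n_donors`; the ATT range is in `attr(, "range")`.
#' @export
leave_one_out <- function(ds, predictors = predictor_spec(),
                          control = scm_control()) {
  validate_panel(ds)
  regions <- unique(ds$region_of[ds$donor_units])
  if (length(regions) < 2) stop("need at least 2 donor regions")
  rows <- list()
  for (r in regions) {
    keep_donors <- ds$donor_units[ds$region_of[ds$donor_units] != r]
    if (length(keep_donors) < 2) {
      warning("skipping region ", r, ": fewer than 2 donors would remain")
      next
    }
    ds_r <- reassign_treated(ds, ds$treated_units,
                             keep_units = c(ds$treated_units, keep_donors))
    fr <- fit_scm(ds_r, predictors, control)
    rows[[r]] <- data.frame(region = r, att = fr$att,
                            pre_rmspe = fr$pre_rmspe,
                            n_donors = length(keep_donors),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "range") <- range(out$att)
  class(out) <- c("loo_result", "data.frame")
  out
}

#' Robustness report across estimators
#'
#' Runs the five estimators on the identical panel — aggregate synthetic
#' control, per-unit synthetic control, per-unit synthetic control + DiD,
#' two-way fixed-effects DiD, and Mahalanobis matching + DiD — plus the
#' leave-one-region-out check, and tabulates ATT and p-value per variant.
#' Placebo-test p-values for the two synthetic-control variants are computed
#' when `B > 0` (and are `NA` otherwise); regression-based variants use
#' cluster-robust p-values.
#'
#' @param ds a [panel_dataset()].
#' @param predictors a [predictor_spec()].
#' @param control an [scm_control()].
#' @param B placebo draws for the synthetic-control p-values (0 disables).
#' @param seed placebo seed.
#' @return an object of class `robustness_report`: `table` (data frame of
#'   method, att, p_value), `loo`, and the individual fit objects.
#' @export
robustness_report <- function(ds, predictors = predictor_spec(),
                              control = scm_control(), B = 0, seed = 1L) {
  agg <- fit_scm(ds, predictors, control)
  per <- scm_per_unit(ds, predictors, control)
  hyb <- scm_plus_did(ds, per)
  did <- did_estimate(ds)
  matched <- match_units(ds, seed = seed)
  mdid <- did_estimate(matched)
  p_agg <- p_per <- NA_real_
  plc <- NULL
  if (B > 0) {
    plc <- run_placebos(ds, agg, B = B, seed = seed,
                        predictors = predictors, control = control)
    p_agg <- plc$p_two_sided
    p_per <- placebo_pvalue(per$att, plc$placebo_atts)
  }
  tab <- data.frame(
    method = c("scm_aggregate", "scm_per_unit", "scm_per_unit_plus_did",
               "did", "matching_did"),
    att = c(agg$att, per$att, hyb$att, did$att, mdid$att),
    p_value = c(p_agg, p_per, hyb$p_value, did$p_value, mdid$p_value),
    stringsAsFactors = FALSE
  )
  loo <- leave_one_out(ds, predictors, control)
  structure(list(table = tab, loo = loo, scm = agg, per_unit = per,
                 hybrid = hyb, did = did, matching_did = mdid,
                 matched_panel = matched, placebos = plc),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("robustness_report: estimated ATTs across methods\n")
  print(transform(x$table, att = round(att, 4), p_value = round(p_value, 4)))
  cat("leave-one-region-out ATT range: [",
      paste(round(attr(x$loo, "range"), 4), collapse = ", "), "]\n")
  invisible(x)
}
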