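#' Balanced unit-by-period panel for synthetic control analysis
#'
#' Constructs and validates the core data container: a balanced panel of
#' outcomes (risk-adjusted mortality in percentage points) and nonnegative
#' per-period frequency weights (patient counts), together with a unit-level
#' region map, time-invariant covariates, the set of treated units, and the
#' last pre-treatment period `T0`.
#'
#' @param outcome numeric matrix, units x periods, with unit row names and
#'   period column names. Column order is the time order.
#' @param freq numeric matrix of nonnegative frequency weights (patient
#'   counts), same shape and dimnames as `outcome`.
#' @param treated_units character vector of treated unit ids (the `K1`
#'   treated units); all remaining units form the donor pool.
#' @param region_of named character vector mapping every unit id to a region
#'   label.
#' @param cut_period period label (a column name of `outcome`) of the last
#'   pre-treatment period, so treatment is active for periods after it.
#' @param covariates numeric matrix, units x k_z, of time-invariant unit
#'   covariates (may have zero columns). Row names must match the units.
#'
#' @return An object of class `panel_dataset`: a list with elements `units`,
#'   `periods`, `cut` (integer index of the last pre period), `cut_period`,
#'   `outcome`, `freq`, `treated_units`, `donor_units`, `region_of`,
#'   `covariates`.
#' @export
panel_dataset <- function(outcome, freq, treated_units, region_of, cut_period,
                          covariates = NULL) {
  stopifnot(is.matrix(outcome), is.numeric(outcome))
  units <- rownames(outcome)
  periods <- colnames(outcome)
  if (is.null(units) || is.null(periods))
    stop("`outcome` must carry unit row names and period column names")
  if (is.null(covariates)) {
    covariates <- matrix(numeric(0), nrow = length(units), ncol = 0,
                         dimnames = list(units, NULL))
  }
  ds <- structure(list(
    units = units,
    periods = periods,
    cut = match(as.character(cut_period), periods),
    cut_period = as.character(cut_period),
    outcome = outcome,
    freq = freq,
    treated_units = as.character(treated_units),
    donor_units = setdiff(units, as.character(treated_units)),
    region_of = region_of[units],
    covariates = covariates
  ), class = "panel_dataset")
  validate_panel(ds)
}

#' Validate a `panel_dataset`
#'
#' Checks balance, the position of the treatment cut, disjointness of treated
#' and donor units, nonnegative frequencies, and positive total treated
#' frequency in every period.
#'
#' @param ds a `panel_dataset`.
#' @return `ds`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_panel <- function(ds) {
  stopifnot(inherits(ds, "panel_dataset"))
  if (anyNA(ds$outcome) || anyNA(ds$freq)) {
    bad <- which(is.na(ds$outcome) | is.na(ds$freq), arr.ind = TRUE)
    stop("panel is not balanced; missing cells: ",
         paste(sprintf("(%s, %s)", rownames(ds$outcome)[bad[, 1]],
                       colnames(ds$outcome)[bad[, 2]]), collapse = ", "))
  }
  if (!identical(dim(ds$outcome), dim(ds$freq)))
    stop("`outcome` and `freq` must have identical dimensions")
  if (is.na(ds$cut)) stop("`cut_period` is not a period of the panel")
  if (ds$cut < 1 || ds$cut >= length(ds$periods))
    stop("cut period must satisfy 1 <= T0 < T")
  if (length(ds$treated_units) == 0) stop("no treated units")
  if (!all(ds$treated_units %in% ds$units))
    stop("treated units absent from panel: ",
         paste(setdiff(ds$treated_units, ds$units), collapse = ", "))
  if (any(ds$freq < 0)) stop("frequency weights must be nonnegative")
  trt_tot <- colSums(ds$freq[ds$treated_units, , drop = FALSE])
  if (any(trt_tot <= 0))
    stop("total treated frequency is zero in period(s): ",
         paste(ds$periods[trt_tot <= 0], collapse = ", "))
  if (anyNA(ds$region_of) || is.null(names(ds$region_of)))
    stop("`region_of` must map every unit to a region")
  if (nrow(ds$covariates) != length(ds$units))
    stop("covariate rows must match units")
  ds
}

#' @export
print.panel_dataset <- function(x, ...) {
  cat("panel_dataset:", length(x$units), "units x", length(x$periods),
      "periods\n")
  cat("  treated:", length(x$treated_units), "| donors:",
      length(x$donor_units), "| regions:",
      length(unique(x$region_of)), "\n")
  cat("  last pre-treatment period:", x$cut_period,
      sprintf("(T0 = %d of T = %d)", x$cut, length(x$periods)), "\n")
  if (ncol(x$covariates) > 0)
    cat("  covariates:", paste(colnames(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Read a long-format panel CSV (plus optional covariate CSV)
#'
#' The long file has one row per unit-period with columns
#' `unit, region, period, outcome, freq, treated`; the covariate file has one
#' row per unit (`unit` plus named covariate columns). Periods are ordered by
#' first appearance in the file. Units missing any period are handled by the
#' balance policy: `"drop-unit"` removes them with a report (mirroring the
#' practice of discarding providers that do not contribute observations to
#' every quarter), `"strict"` raises an error naming the missing cells.
#'
#' @param long_csv path to the long panel CSV.
#' @param covariate_csv optional path to the unit-level covariate CSV.
#' @param cut_period label of the last pre-treatment period.
#' @param balance `"drop-unit"` (default) or `"strict"`.
#' @return a validated [panel_dataset()]; units dropped under `"drop-unit"`
#'   are reported via a message and recorded in `attr(ds, "dropped_units")`.
#' @export
read_panel <- function(long_csv, covariate_csv = NULL, cut_period,
                       balance = c("drop-unit", "strict")) {
  balance <- match.arg(balance)
  df <- utils::read.csv(long_csv, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  need <- c("unit", "region", "period", "outcome", "freq", "treated")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("long CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (!is.numeric(df$outcome))
    stop("non-numeric `outcome` values in ", long_csv)
  if (!is.numeric(df$freq)) stop("non-numeric `freq` values in ", long_csv)
  df$unit <- as.character(df$unit)
  df$period <- as.character(df$period)

  periods <- unique(df$period)
  units <- unique(df$unit)
  key <- paste(df$unit, df$period, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicated (unit, period) rows: ",
         paste(utils::head(sub("\r", ", ", key[duplicated(key)]), 5),
               collapse = "; "))

  have <- matrix(FALSE, length(units), length(periods),
                 dimnames = list(units, periods))
  have[cbind(df$unit, df$period)] <- TRUE
  incomplete <- rownames(have)[rowSums(have) < length(periods)]
  if (length(incomplete)) {
    if (balance == "strict") {
      cells <- which(!have, arr.ind = TRUE)
      stop("unbalanced panel under policy 'strict'; missing cells: ",
           paste(sprintf("(%s, %s)", rownames(have)[cells[, 1]],
                         colnames(have)[cells[, 2]]), collapse = ", "))
    }
    message("drop-unit balance policy removed ", length(incomplete),
            " unit(s): ", paste(incomplete, collapse = ", "))
    df <- df[!df$unit %in% incomplete, , drop = FALSE]
    units <- setdiff(units, incomplete)
  }

  fill <- function(col) {
    m <- matrix(NA_real_, length(units), length(periods),
                dimnames = list(units, periods))
    m[cbind(df$unit, df$period)] <- df[[col]]
    m
  }
  outcome <- fill("outcome")
  freq <- fill("freq")
  region_of <- stats::setNames(df$region[!duplicated(df$unit)],
                               df$unit[!duplicated(df$unit)])
  treated_units <- unique(df$unit[df$treated != 0])
  if (length(treated_units) == 0)
    stop("no treated rows in ", long_csv)

  covariates <- NULL
  if (!is.null(covariate_csv)) {
    cv <- utils::read.csv(covariate_csv, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8", check.names = FALSE)
    if (!"unit" %in% names(cv)) stop("covariate CSV lacks `unit` column")
    cv$unit <- as.character(cv$unit)
    unknown <- setdiff(cv$unit, c(units, if (balance == "drop-unit") incomplete))
    if (length(unknown))
      stop("covariate file contains unknown unit(s): ",
           paste(unknown, collapse = ", "))
    cv <- cv[cv$unit %in% units, , drop = FALSE]
    absent <- setdiff(units, cv$unit)
    if (length(absent))
      stop("covariate file lacks unit(s): ", paste(absent, collapse = ", "))
    cols <- setdiff(names(cv), "unit")
    covariates <- as.matrix(cv[match(units, cv$unit), cols, drop = FALSE])
    rownames(covariates) <- units
    storage.mode(covariates) <- "double"
  }

  ds <- panel_dataset(outcome, freq, treated_units, region_of, cut_period,
                      covariates)
  attr(ds, "dropped_units") <- if (length(incomplete)) incomplete else character(0)
  ds
}

#' Write a panel to long CSV (plus optional covariate CSV)
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(ds), ...)` reproduces
#' `ds` field for field. The treatment column holds the active indicator
#' `D_it` (treated unit and period after the cut).
#'
#' @param ds a `panel_dataset`.
#' @param path output path for the long CSV.
#' @param covariate_path optional output path for the covariate CSV; required
#'   when `ds` carries covariates.
#' @return `path`, invisibly.
#' @export
write_panel <- function(ds, path, covariate_path = NULL) {
  validate_panel(ds)
  post <- seq_along(ds$periods) > ds$cut
  df <- data.frame(
    unit = rep(ds$units, each = length(ds$periods)),
    region = rep(ds$region_of, each = length(ds$periods)),
    period = rep(ds$periods, times = length(ds$units)),
    outcome = as.vector(t(ds$outcome)),
    freq = as.vector(t(ds$freq)),
    treated = as.integer(rep(ds$units %in% ds$treated_units,
                             each = length(ds$periods)) & post),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  if (ncol(ds$covariates) > 0) {
    if (is.null(covariate_path))
      stop("`covariate_path` required: dataset carries covariates")
    cv <- data.frame(unit = ds$units, ds$covariates, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.csv(cv, covariate_path, row.names = FALSE,
                     fileEncoding = "UTF-8")
  }
  invisible(path)
}

# Internal: restrict a panel to a new treated set / donor pool without
# touching the stored matrices. Used by placebo draws and leave-one-out.
reassign_treated <- function(ds, treated_units, keep_units = NULL) {
  units <- if (is.null(keep_units)) ds$units else keep_units
  out <- ds
  out$units <- units
  out$outcome <- ds$outcome[units, , drop = FALSE]
  out$freq <- ds$freq[units, , drop = FALSE]
  out$covariates <- ds$covariates[units, , drop = FALSE]
  out$region_of <- ds$region_of[units]
  out$treated_units <- treated_units
  out$donor_units <- setdiff(units, treated_units)
  out
}
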