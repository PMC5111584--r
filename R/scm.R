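#' Aggregate the treated units into a single treated region
#'
#' Outcomes are averaged across treated units with per-period patient-count
#' weights, \eqn{\bar Y_t = \sum_i Y_{it} f_{it} / \sum_i f_{it}}; covariates
#' are averaged with each unit's pre-period mean patient count as a
#' time-invariant weight; \eqn{\bar f_t} is the total treated patient count.
#'
#' @param ds a [panel_dataset()].
#' @return a list with `y_bar` (length-T outcome of the treated region),
#'   `z_bar` (frequency-weighted covariate means, length k_z) and `f_bar`
#'   (length-T total treated patient counts).
#' @export
aggregate_treated <- function(ds) {
  validate_panel(ds)
  trt <- ds$treated_units
  Y <- ds$outcome[trt, , drop = FALSE]
  f <- ds$freq[trt, , drop = FALSE]
  f_bar <- colSums(f)
  y_bar <- colSums(Y * f) / f_bar
  w_unit <- rowMeans(f[, seq_len(ds$cut), drop = FALSE])
  z_bar <- if (ncol(ds$covariates) > 0) {
    as.numeric(crossprod(ds$covariates[trt, , drop = FALSE], w_unit) /
                 sum(w_unit))
  } else numeric(0)
  names(z_bar) <- colnames(ds$covariates)
  list(y_bar = y_bar, z_bar = z_bar, f_bar = f_bar)
}

#' Specify the predictors entering the synthetic-control distance metric
#'
#' @param covariates `TRUE` (all panel covariates), `FALSE`/`NULL` (none), or
#'   a character vector of covariate names.
#' @param pre_outcomes `"all"` (every pre-treatment period, the default) or an
#'   integer vector of pre-period indices.
#' @return a `predictor_spec` list.
#' @export
predictor_spec <- function(covariates = TRUE, pre_outcomes = "all") {
  structure(list(covariates = covariates, pre_outcomes = pre_outcomes),
            class = "predictor_spec")
}

#' Build the donor matching problem
#'
#' Assembles the treated-region predictor vector `X1` (selected covariates
#' plus selected pre-period outcomes) and the corresponding `k x J` donor
#' matrix `X0`, standardises each predictor row to unit standard deviation
#' across the pooled treated region + donors (so the importance weights `V`
#' are scale-free), and carries the raw pre/post outcome matrices needed for
#' prediction-error evaluation. Zero-variance predictor rows are dropped with
#' a warning and recorded.
#'
#' @param ds a [panel_dataset()].
#' @param predictors a [predictor_spec()].
#' @return an object of class `donor_problem` with elements `X1`, `X0`
#'   (standardised), `scale` (the per-row sd used), `Y1_pre`, `Y0_pre`,
#'   `Y0_post`, `Y0` (full donor outcomes), `y_bar`, `f_bar`, `donors`,
#'   `dropped` (names of dropped rows), `cut`.
#' @export
build_problem <- function(ds, predictors = predictor_spec()) {
  stopifnot(inherits(predictors, "predictor_spec"))
  agg <- aggregate_treated(ds)
  donors <- ds$donor_units
  if (length(donors) < 1) stop("donor pool is empty")
  T0 <- ds$cut

  covs <- predictors$covariates
  cov_names <- if (isTRUE(covs)) colnames(ds$covariates)
    else if (is.character(covs)) covs else character(0)
  if (length(setdiff(cov_names, colnames(ds$covariates))))
    stop("unknown covariate(s) in predictor spec")
  pre_idx <- if (identical(predictors$pre_outcomes, "all")) seq_len(T0)
    else as.integer(predictors$pre_outcomes)
  if (length(pre_idx) && (min(pre_idx) < 1 || max(pre_idx) > T0))
    stop("pre-outcome indices must lie in 1..T0")

  X1 <- c(agg$z_bar[cov_names], agg$y_bar[pre_idx])
  X0 <- rbind(t(ds$covariates[donors, cov_names, drop = FALSE]),
              t(ds$outcome[donors, pre_idx, drop = FALSE]))
  rn <- c(cov_names, paste0("pre_", ds$periods[pre_idx]))
  rownames(X0) <- rn
  names(X1) <- rn
  if (nrow(X0) == 0) stop("predictor spec selects no predictors")

  sds <- apply(cbind(X1, X0), 1, stats::sd)
  dropped <- rn[sds <= .Machine$double.eps^0.5]
  if (length(dropped)) {
    warning("dropping zero-variance predictor row(s): ",
            paste(dropped, collapse = ", "))
    keep <- setdiff(rn, dropped)
    X1 <- X1[keep]; X0 <- X0[keep, , drop = FALSE]; sds <- sds[keep]
  }
  if (length(X1) == 0) stop("all predictor rows have zero variance")
  X1s <- X1 / sds
  X0s <- X0 / sds

  structure(list(
    X1 = X1s, X0 = X0s, scale = sds,
    Y1_pre = agg$y_bar[seq_len(T0)],
    Y0_pre = t(ds$outcome[donors, seq_len(T0), drop = FALSE]),
    Y0_post = t(ds$outcome[donors, -seq_len(T0), drop = FALSE]),
    Y0 = t(ds$outcome[donors, , drop = FALSE]),
    y_bar = agg$y_bar, f_bar = agg$f_bar,
    donors = donors, dropped = dropped, cut = T0
  ), class = "donor_problem")
}

# Exact solver for min ||A w - b||^2 subject to w >= 0, sum(w) = 1.
# Active-set method in the style of Lawson-Hanson NNLS, adapted to the
# simplex: solve the equality-constrained KKT system on the current support,
# step to the boundary when a support weight would go negative, and add the
# most violating zero-weight coordinate until the dual feasibility condition
# g_j >= lambda holds on the inactive set. Rank-deficient KKT systems are
# resolved by the minimum-norm (pseudoinverse) solution, which keeps the
# solver deterministic when the optimum is non-unique.
simplex_lsq <- function(A, b, tol = 1e-11) {
  J <- ncol(A)
  if (J == 1) {
    w <- 1
    return(list(w = w, objective = sum((A - b)^2)))
  }
  H <- crossprod(A)
  g0 <- as.numeric(crossprod(A, b))
  kkt <- function(S) {
    m <- length(S)
    K <- rbind(cbind(2 * H[S, S, drop = FALSE], -1), c(rep(1, m), 0))
    rhs <- c(2 * g0[S], 1)
    sol <- tryCatch(solve(K, rhs),
                    error = function(e) as.numeric(MASS::ginv(K) %*% rhs))
    list(w = sol[seq_len(m)], lam = sol[m + 1])
  }
  w <- rep(1 / J, J)
  S <- seq_len(J)
  for (it in seq_len(6L * J + 50L)) {
    cs <- kkt(S)
    ws <- cs$w
    if (all(ws >= -tol)) {
      w[] <- 0
      w[S] <- pmax(ws, 0)
      w <- w / sum(w)
      grad <- as.numeric(2 * (H %*% w - g0))
      out <- setdiff(seq_len(J), S)
      if (!length(out)) break
      viol <- out[grad[out] < cs$lam - 1e-9]
      if (!length(viol)) break
      S <- sort(c(S, viol[which.min(grad[viol])]))
    } else {
      wS <- w[S]
      d <- ws - wS
      neg <- which(ws < -tol & d < 0)
      step <- min(wS[neg] / (wS[neg] - ws[neg]))
      wS <- pmax(wS + step * d, 0)
      w[] <- 0
      w[S] <- wS
      S <- S[wS > tol]
      if (!length(S)) {
        S <- seq_len(J)
        w <- rep(1 / J, J)
      }
    }
  }
  resid <- as.numeric(A %*% w) - b
  list(w = w, objective = sum(resid^2))
}

#' Solve for donor weights at a fixed importance matrix V
#'
#' Minimises the distance metric
#' \eqn{(X_1 - X_0 W)' V (X_1 - X_0 W)} over the simplex
#' \eqn{W \ge 0, \sum_j w_j = 1} — a convex quadratic program, solved exactly
#' by an active-set method.
#'
#' @param p a [build_problem()] result.
#' @param V nonnegative importance weights over the `k` predictor rows,
#'   summing to 1 (the diagonal of the V matrix).
#' @return a list with `w` (named donor weights) and `objective` (the achieved
#'   distance-metric value).
#' @export
solve_weights <- function(p, V) {
  stopifnot(inherits(p, "donor_problem"))
  k <- length(p$X1)
  if (length(V) != k) stop("V must have length ", k)
  if (any(V < 0) || abs(sum(V) - 1) > 1e-8)
    stop("V must be nonnegative and sum to 1")
  sv <- sqrt(V)
  sol <- simplex_lsq(p$X0 * sv, p$X1 * sv)
  names(sol$w) <- p$donors
  sol
}

pre_rmspe_of <- function(p, w)
  sqrt(mean((p$Y1_pre - as.numeric(p$Y0_pre %*% w))^2))

#' Control settings for the nested V/W optimisation
#'
#' @param n_random_starts number of random Dirichlet starting points for V, in
#'   addition to the uniform start and one one-hot start per predictor.
#' @param maxit maximum Nelder-Mead iterations per start.
#' @param reltol relative convergence tolerance for Nelder-Mead.
#' @param seed integer seed for the random starts.
#' @param fast_v if `TRUE`, skip the nested optimisation and use `v_init`
#'   (default uniform) directly — used for large placebo/replication studies
#'   where full re-optimisation per fit is not warranted.
#' @param v_init optional fixed V (nonnegative, sums to 1) used when
#'   `fast_v = TRUE`, or as an extra start otherwise.
#' @param att_weighting `"per-period"` (default): post-period effects averaged
#'   with per-period total treated patient counts; `"cumulative"`: running
#'   totals of those counts.
#' @return an `scm_control` list.
#' @export
scm_control <- function(n_random_starts = 5, maxit = 400, reltol = 1e-10,
                        seed = 1L, fast_v = FALSE, v_init = NULL,
                        att_weighting = c("per-period", "cumulative")) {
  structure(list(n_random_starts = n_random_starts, maxit = maxit,
                 reltol = reltol, seed = as.integer(seed), fast_v = fast_v,
                 v_init = v_init, att_weighting = match.arg(att_weighting)),
            class = "scm_control")
}

#' Jointly choose V and W to minimise pre-treatment prediction error
#'
#' Nested optimisation: for a candidate V the inner problem returns
#' `W(V) = solve_weights(p, V)`, and the outer objective is the root mean
#' squared prediction error of the pre-treatment outcomes,
#' `pre_rmspe(W(V))`. The outer problem is non-convex, so a multi-start
#' derivative-free (Nelder-Mead) search is used over a softmax
#' parameterisation of the simplex: a uniform start, one one-hot start per
#' predictor, and seeded random Dirichlet starts.
#'
#' @param p a [build_problem()] result.
#' @param control an [scm_control()].
#' @return a list with `V` (named), `W` (named), `pre_rmspe`, `objective`
#'   (the distance metric at the optimum) and `starts` (a data frame of all
#'   starting points' achieved pre-RMSPE, for non-uniqueness diagnostics).
#' @export
optimize_V <- function(p, control = scm_control()) {
  stopifnot(inherits(p, "donor_problem"))
  k <- length(p$X1)
  softmax <- function(par) {
    e <- exp(par - max(par))
    e / sum(e)
  }
  eval_V <- function(V) pre_rmspe_of(p, solve_weights(p, V)$w)

  if (k == 1) {
    V <- 1
  } else if (isTRUE(control$fast_v)) {
    V <- if (is.null(control$v_init)) rep(1 / k, k) else control$v_init
  } else {
    # The outer objective is non-convex and, when the inner QP optimum is
    # non-unique (k < J), only piecewise-continuous in V, so a local search
    # alone is unreliable. Strategy: a deterministic coarse sweep of the V
    # simplex (dense 1-D grid for k = 2, seeded Dirichlet sample otherwise)
    # supplies global candidates; Nelder-Mead in a softmax parameterisation
    # polishes the structured starts; the exact simplex vertices and
    # hard-thresholded search optima are re-evaluated because the QP
    # tie-break can change discontinuously at the boundary of the V simplex,
    # which the softmax parameterisation only approaches.
    coarse <- if (k == 2) {
      lapply(seq(0, 1, by = 0.01), function(a) c(a, 1 - a))
    } else {
      withr::with_seed(control$seed + 1L, {
        m <- matrix(stats::rexp(200 * k), ncol = k)
        lapply(seq_len(200), function(i) m[i, ] / sum(m[i, ]))
      })
    }
    coarse_vals <- vapply(coarse, eval_V, numeric(1))
    best_coarse <- coarse[order(coarse_vals)[seq_len(min(3, length(coarse)))]]

    starts <- rbind(rep(0, k), diag(8, k))
    extra <- withr::with_seed(control$seed, {
      m <- matrix(stats::rexp(control$n_random_starts * k), ncol = k)
      log(m / rowSums(m))
    })
    starts <- rbind(starts, extra,
                    do.call(rbind, lapply(best_coarse,
                                          function(v) log(pmax(v, 1e-12)))))
    if (!is.null(control$v_init))
      starts <- rbind(starts, log(pmax(control$v_init, 1e-12)))
    res <- apply(starts, 1, function(par0) {
      opt <- stats::optim(par0, function(par) eval_V(softmax(par)),
                          method = "Nelder-Mead",
                          control = list(maxit = control$maxit,
                                         reltol = control$reltol))
      list(V = softmax(opt$par), value = opt$value)
    })
    cand <- lapply(res, `[[`, "V")
    cand <- c(cand, lapply(cand, function(v) {
      v[v < 1e-6] <- 0
      if (sum(v) == 0) v else v / sum(v)
    }))
    cand <- c(cand, lapply(seq_len(k), function(i) {
      v <- numeric(k); v[i] <- 1; v
    }), list(rep(1 / k, k)), coarse)
    if (!is.null(control$v_init)) cand <- c(cand, list(control$v_init))
    vals <- vapply(cand, eval_V, numeric(1))
    V <- cand[[which.min(vals)]]
    start_tab <- data.frame(start = seq_along(vals), pre_rmspe = vals)
  }
  sol <- solve_weights(p, V)
  names(V) <- names(p$X1)
  out <- list(V = V, W = sol$w, pre_rmspe = pre_rmspe_of(p, sol$w),
              objective = sol$objective)
  out$starts <- if (exists("start_tab", inherits = FALSE)) start_tab else NULL
  out
}

#' Fit the aggregate synthetic control estimator
#'
#' Aggregates the treated units into a treated region, chooses the importance
#' weights V and donor weights W by nested pre-treatment RMSPE minimisation,
#' forms the counterfactual \eqn{\hat{\bar Y}^N_t = \sum_j w_j Y_{jt}}, and
#' reports per-period gaps, the pre-treatment fit diagnostic, and the ATT as
#' the patient-count-weighted average of the post-period gaps.
#'
#' @param ds a [panel_dataset()].
#' @param predictors a [predictor_spec()].
#' @param control an [scm_control()].
#' @return an object of class `scm_fit` with elements `w`, `v`, `gaps`
#'   (length-T, treated minus synthetic), `synthetic` (length-T counterfactual
#'   series), `y_bar`, `pre_rmspe`, `att`, `att_weights`, `objective`,
#'   `dropped_predictors`, `periods`, `cut`, `starts`.
#' @export
fit_scm <- function(ds, predictors = predictor_spec(),
                    control = scm_control()) {
  p <- build_problem(ds, predictors)
  opt <- optimize_V(p, control)
  synthetic <- as.numeric(p$Y0 %*% opt$W)
  gaps <- p$y_bar - synthetic
  T0 <- p$cut
  post <- seq_along(gaps) > T0
  fw <- p$f_bar[post]
  if (control$att_weighting == "cumulative") fw <- cumsum(fw)
  att <- sum(gaps[post] * fw) / sum(fw)
  structure(list(
    w = opt$W, v = opt$V, gaps = stats::setNames(gaps, ds$periods),
    synthetic = stats::setNames(synthetic, ds$periods),
    y_bar = p$y_bar, f_bar = p$f_bar,
    pre_rmspe = opt$pre_rmspe, att = att,
    att_weights = stats::setNames(fw / sum(fw), ds$periods[post]),
    objective = opt$objective, dropped_predictors = p$dropped,
    periods = ds$periods, cut = T0, starts = opt$starts,
    control = control
  ), class = "scm_fit")
}

#' @export
print.scm_fit <- function(x, ...) {
  cat("scm_fit: synthetic control for an aggregated treated region\n")
  cat(sprintf("  ATT (post-period, frequency-weighted): %.4f\n", x$att))
  cat(sprintf("  pre-treatment RMSPE: %.6g\n", x$pre_rmspe))
  nz <- sort(x$w[x$w > 1e-4], decreasing = TRUE)
  cat("  donors with weight > 1e-4:", length(nz), "\n")
  print(round(utils::head(nz, 8), 4))
  invisible(x)
}
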