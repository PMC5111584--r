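#' Configuration for the factor-model panel generator
#'
#' The generator draws balanced unit-by-period panels from the interactive
#' fixed-effects outcome model
#' \deqn{Y_{jt} = \delta_t + \lambda_t' \mu_j + \theta_t' Z_j + \epsilon_{jt}
#'       + \alpha_{t} D_{jt},}
#' where `delta` are common time effects, `mu_j` are unobserved unit factor
#' loadings with time-varying coefficients `lambda_t`, `Z_j` are observed
#' time-invariant covariates with time-varying coefficients `theta_t`,
#' `eps` is transitory noise, and the treatment effect `alpha` is added for
#' treated units after the cut period. Difference-in-differences is unbiased
#' here exactly when `lambda_t` is constant over time or the treated and donor
#' loading distributions coincide; a trending `lambda_t` combined with
#' `treated_mu_shift != 0` violates parallel trends by construction.
#'
#' @param J_donors number of donor units.
#' @param K1_treated number of treated units.
#' @param n_regions number of donor regions (donors are assigned round-robin;
#'   all treated units share the region `"treated"`).
#' @param T_periods total number of periods.
#' @param T0 last pre-treatment period (integer index, `1 <= T0 < T`).
#' @param r number of unobserved factors (0 allowed).
#' @param delta length-`T_periods` vector of common time effects; default is a
#'   mild seasonal pattern with a slow downward trend, on the percentage-point
#'   scale of risk-adjusted mortality.
#' @param lambda `T_periods` x `r` matrix of factor-loading coefficients;
#'   default constant 1 per factor (parallel trends hold).
#' @param mu_scale standard deviation of unit factor loadings `mu_j`.
#' @param k_z number of observed covariates.
#' @param theta `T_periods` x `k_z` matrix of covariate coefficients; default
#'   smooth distinct paths per covariate.
#' @param sigma_eps standard deviation of the transitory shock.
#' @param alpha treatment effect: scalar, or vector of length `T_periods - T0`
#'   for per-period effects.
#' @param freq_mean mean of the truncated-Poisson (at >= 1) patient-count draw
#'   per unit-period.
#' @param treated_mu_shift offset added to the mean of treated units' factor
#'   loadings (controls unobserved confounding).
#' @param treated_hull_weights optional vector of donor weights (length
#'   `J_donors`, nonnegative, summing to 1). When supplied, every treated
#'   unit's `(mu, Z)` is set exactly to that convex combination of the donor
#'   `(mu, Z)` values, so the treated region lies inside the donor convex hull
#'   and a zero-pre-error synthetic control exists by construction.
#' @param seed integer seed; the draw is deterministic given the config.
#' @return an object of class `factor_config`.
#' @export
factor_config <- function(J_donors = 30, K1_treated = 6, n_regions = 9,
                          T_periods = 12, T0 = 6, r = 1,
                          delta = NULL, lambda = NULL, mu_scale = 1,
                          k_z = 2, theta = NULL, sigma_eps = 0.2,
                          alpha = 0, freq_mean = 150,
                          treated_mu_shift = 0,
                          treated_hull_weights = NULL, seed = 1L) {
  stopifnot(T0 >= 1, T0 < T_periods, r >= 0, sigma_eps >= 0,
            J_donors >= 1, K1_treated >= 1, n_regions >= 1, freq_mean >= 1)
  tt <- seq_len(T_periods)
  if (is.null(delta))
    delta <- 2 + 0.5 * sin(2 * pi * tt / 4) - 0.05 * tt
  if (is.null(lambda))
    lambda <- matrix(1, T_periods, max(r, 1))[, seq_len(r), drop = FALSE]
  lambda <- as.matrix(lambda)
  if (r > 0 && !all(dim(lambda) == c(T_periods, r)))
    stop("`lambda` must be a T x r matrix")
  if (is.null(theta) && k_z > 0)
    theta <- sapply(seq_len(k_z),
                    function(m) 0.4 * cos(2 * pi * tt / (3 + 2 * m)) + 0.2 * m)
  if (k_z > 0) {
    theta <- as.matrix(theta)
    if (!all(dim(theta) == c(T_periods, k_z)))
      stop("`theta` must be a T x k_z matrix")
  } else theta <- matrix(0, T_periods, 0)
  if (length(delta) != T_periods) stop("`delta` must have length T")
  n_post <- T_periods - T0
  if (!length(alpha) %in% c(1L, n_post))
    stop("`alpha` must be a scalar or a length T - T0 vector")
  if (!is.null(treated_hull_weights)) {
    w <- treated_hull_weights
    if (length(w) != J_donors || any(w < 0) || abs(sum(w) - 1) > 1e-10)
      stop("`treated_hull_weights` must be a simplex vector of length J_donors")
  }
  structure(list(
    J_donors = J_donors, K1_treated = K1_treated, n_regions = n_regions,
    T_periods = T_periods, T0 = T0, r = r, delta = delta, lambda = lambda,
    mu_scale = mu_scale, k_z = k_z, theta = theta, sigma_eps = sigma_eps,
    alpha = alpha, freq_mean = freq_mean,
    treated_mu_shift = treated_mu_shift,
    treated_hull_weights = treated_hull_weights, seed = as.integer(seed)
  ), class = "factor_config")
}

#' Named scenario configurations
#'
#' Four fully seeded study conditions used throughout the test suite:
#' \describe{
#'   \item{`"parallel"`}{constant factor loadings (parallel trends hold), a
#'     level difference between treated and donor units, `alpha = 1`, noise
#'     sd 0.2: DiD and SCM are both consistent.}
#'   \item{`"hull"`}{noiseless; every treated unit's `(mu, Z)` is a fixed
#'     convex combination of three designated donors, `alpha = 2`: a perfect
#'     synthetic control exists and the true effect is exactly recoverable.}
#'   \item{`"divergent"`}{trending loadings plus a treated loading shift:
#'     parallel trends fail, DiD is biased, SCM can reweight donors to match
#'     the treated loadings. `alpha = 1`, noise sd 0.1.}
#'   \item{`"null"`}{no effect, no confounding shift, trending loadings:
#'     treated and donor units are exchangeable, the reference condition for
#'     placebo-test calibration. Smaller panel (20 donors, 4 treated) so that
#'     replication studies of the placebo test stay cheap.}
#' }
#'
#' @param scenario one of `"parallel"`, `"hull"`, `"divergent"`, `"null"`.
#' @param seed integer seed.
#' @param ... overrides passed to [factor_config()].
#' @return a `factor_config`.
#' @export
scenario_config <- function(scenario = c("parallel", "hull", "divergent",
                                         "null"),
                            seed = 1L, ...) {
  scenario <- match.arg(scenario)
  tt <- seq_len(12)
  base <- switch(scenario,
    parallel = list(J_donors = 30, K1_treated = 6, alpha = 1,
                    sigma_eps = 0.2, treated_mu_shift = 1,
                    lambda = matrix(1, 12, 1),
                    theta = matrix(0.3, 12, 2)),
    hull = {
      hw <- c(0.2, 0.5, 0.3, rep(0, 21))
      list(J_donors = 24, K1_treated = 3, alpha = 2, sigma_eps = 0,
           lambda = matrix(seq(0.5, 2, length.out = 12), 12, 1),
           theta = cbind(0.4 * cos(2 * pi * tt / 5),
                         0.3 * sin(2 * pi * tt / 7) + 0.2),
           treated_hull_weights = hw)
    },
    divergent = list(J_donors = 30, K1_treated = 6, alpha = 1,
                     sigma_eps = 0.1, treated_mu_shift = 1,
                     lambda = matrix(seq(0.5, 2, length.out = 12), 12, 1)),
    null = list(J_donors = 20, K1_treated = 4, n_regions = 5, alpha = 0,
                sigma_eps = 0.2, treated_mu_shift = 0,
                lambda = matrix(seq(0.5, 2, length.out = 12), 12, 1))
  )
  over <- list(...)
  args <- utils::modifyList(c(base, list(seed = seed)), over)
  cfg <- do.call(factor_config, args)
  attr(cfg, "scenario") <- scenario
  cfg
}

#' Generate a panel from the factor model
#'
#' Draws unit factor loadings, covariates, noise and truncated-Poisson patient
#' counts, assembles outcomes from the factor model, and adds the treatment
#' effect for treated units after the cut. Deterministic given the config
#' (including its seed).
#'
#' @param cfg a [factor_config()].
#' @return a list with elements `panel` (a [panel_dataset()]) and `truth`
#'   (the realised `alpha` path, `mu`, `Z`, `lambda`, `theta`, `delta`, and
#'   any hull weights) for use as ground truth in simulation studies.
#' @export
generate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "factor_config"))
  withr::with_seed(cfg$seed, {
    J <- cfg$J_donors; K1 <- cfg$K1_treated
    Tt <- cfg$T_periods; r <- cfg$r; kz <- cfg$k_z
    n <- J + K1
    donor_ids <- sprintf("D%02d", seq_len(J))
    treated_ids <- sprintf("T%02d", seq_len(K1))
    units <- c(treated_ids, donor_ids)

    mu_d <- matrix(stats::rnorm(J * max(r, 1), 0, cfg$mu_scale), J)[
      , seq_len(r), drop = FALSE]
    Z_d <- matrix(stats::rnorm(J * max(kz, 1)), J)[, seq_len(kz), drop = FALSE]
    if (!is.null(cfg$treated_hull_weights)) {
      w <- cfg$treated_hull_weights
      mu_t <- matrix(rep(crossprod(mu_d, w), each = K1), K1)
      Z_t <- matrix(rep(crossprod(Z_d, w), each = K1), K1)
    } else {
      mu_t <- matrix(stats::rnorm(K1 * max(r, 1), cfg$treated_mu_shift,
                                  cfg$mu_scale), K1)[, seq_len(r), drop = FALSE]
      Z_t <- matrix(stats::rnorm(K1 * max(kz, 1)), K1)[, seq_len(kz),
                                                       drop = FALSE]
    }
    mu <- rbind(mu_t, mu_d)
    Z <- rbind(Z_t, Z_d)
    rownames(mu) <- rownames(Z) <- units
    if (kz > 0) colnames(Z) <- sprintf("z%d", seq_len(kz))

    base <- matrix(rep(cfg$delta, each = n), n)           # delta_t
    if (r > 0) base <- base + mu %*% t(cfg$lambda)        # lambda_t' mu_j
    if (kz > 0) base <- base + Z %*% t(cfg$theta)         # theta_t' Z_j
    eps <- matrix(stats::rnorm(n * Tt, 0, cfg$sigma_eps), n)
    Y <- base + eps

    n_post <- Tt - cfg$T0
    alpha_path <- rep(cfg$alpha, length.out = n_post)
    D <- matrix(0, n, Tt)
    D[units %in% treated_ids, (cfg$T0 + 1):Tt] <- 1
    Y <- Y + D * matrix(c(rep(0, cfg$T0), alpha_path), n, Tt, byrow = TRUE)

    freq <- matrix(1 + stats::rpois(n * Tt, cfg$freq_mean - 1), n)
    dimnames(Y) <- dimnames(freq) <- list(units, sprintf("q%02d", seq_len(Tt)))

    region_of <- stats::setNames(
      c(rep("treated", K1),
        sprintf("C%d", rep_len(seq_len(cfg$n_regions), J))),
      units)
    ds <- panel_dataset(Y, freq, treated_ids, region_of,
                        cut_period = sprintf("q%02d", cfg$T0),
                        covariates = Z)
    list(panel = ds,
         truth = list(alpha = alpha_path, mu = mu, Z = Z,
                      lambda = cfg$lambda, theta = cfg$theta,
                      delta = cfg$delta,
                      hull_weights = cfg$treated_hull_weights))
  })
}

#' Generate synthetic patient-level records for a panel
#'
#' For every unit-period cell, draws `freq` patients with independent
#' covariates and Bernoulli death outcomes from a logistic model
#' `logit P(died) = intercept + coefs' x + shift[unit, period]`. Used to
#' exercise the risk-adjustment stage; empirical cell death rates converge to
#' the model probabilities as the patient counts grow.
#'
#' @param ds a [panel_dataset()]; its `freq` matrix gives the number of
#'   patients per cell.
#' @param intercept logit-scale intercept.
#' @param coefs named numeric vector of covariate coefficients; covariates are
#'   drawn as standard normals under those names (empty vector allowed).
#' @param shift unit x period matrix of logit-scale baseline shifts (default
#'   all zero); dimnames must match the panel when supplied.
#' @param seed integer seed.
#' @return a `data.frame` of class `patient_table` with columns `unit`,
#'   `period`, `died`, and one column per covariate.
#' @export
generate_patients <- function(ds, intercept = stats::qlogis(0.2),
                              coefs = c(age = 0.5, sex = -0.2,
                                        comorbidity = 0.8),
                              shift = NULL, seed = 1L) {
  validate_panel(ds)
  if (is.null(shift))
    shift <- matrix(0, length(ds$units), length(ds$periods),
                    dimnames = dimnames(ds$outcome))
  withr::with_seed(seed, {
    counts <- ds$freq
    n_tot <- sum(counts)
    unit <- rep(rep(ds$units, times = length(ds$periods)), as.vector(counts))
    period <- rep(rep(ds$periods, each = length(ds$units)), as.vector(counts))
    kx <- length(coefs)
    X <- matrix(stats::rnorm(n_tot * max(kx, 1)), n_tot)[, seq_len(kx),
                                                         drop = FALSE]
    colnames(X) <- names(coefs)
    eta <- intercept + as.vector(X %*% coefs) + shift[cbind(unit, period)]
    p <- stats::plogis(eta)
    if (any(!is.finite(eta)))
      stop("non-finite linear predictor: check `shift` and coefficients")
    died <- stats::rbinom(n_tot, 1, p)
    pt <- data.frame(unit = unit, period = period, died = died, X,
                     stringsAsFactors = FALSE, check.names = FALSE)
    class(pt) <- c("patient_table", "data.frame")
    pt
  })
}
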