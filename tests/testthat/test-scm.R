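test_that("treated aggregation is the patient-count-weighted mean", {
  ds <- toy_panel(2, 2, 4, 2)
  ds$outcome["t1", ] <- 2; ds$outcome["t2", ] <- 4
  ds$freq["t1", ] <- 1; ds$freq["t2", ] <- 3
  agg <- aggregate_treated(ds)
  expect_equal(unname(agg$y_bar), rep(3.5, 4))
  expect_equal(unname(agg$f_bar), rep(4, 4))

  ds$freq["t1", ] <- 3  # equal frequencies -> simple mean
  expect_equal(unname(aggregate_treated(ds)$y_bar), rep(3, 4))
})

test_that("splitting a treated unit into two identical halves leaves the aggregate unchanged", {
  withr::with_seed(2, {
    ds <- toy_panel(1, 3, 5, 3,
                    outcome = matrix(rnorm(20), 4),
                    freq = matrix(8, 4, 5))
    a1 <- aggregate_treated(ds)
    Y <- rbind(ds$outcome["t1", ], ds$outcome)
    f <- rbind(ds$freq["t1", ] / 2, ds$freq)
    f[2, ] <- f[2, ] / 2
    rownames(Y) <- rownames(f) <- c("t1b", rownames(ds$outcome))
    ds2 <- panel_dataset(Y, f, c("t1", "t1b"),
                         stats::setNames(c("treated", ds$region_of),
                                         rownames(Y)),
                         cut_period = ds$cut_period)
    a2 <- aggregate_treated(ds2)
    expect_equal(a2$y_bar, a1$y_bar)
    expect_equal(a2$f_bar, a1$f_bar)
  })
})

test_that("the donor problem has k = k_z + T0 rows and records its scaling", {
  gen <- scenario_panel("parallel", seed = 4)
  p <- build_problem(gen$panel)
  expect_equal(length(p$X1), 2 + 6)
  expect_equal(nrow(p$X0), 2 + 6)
  expect_equal(ncol(p$X0), length(gen$panel$donor_units))
  expect_true(all(p$scale > 0))

  p2 <- build_problem(gen$panel, predictor_spec(covariates = FALSE))
  expect_equal(length(p2$X1), 6)  # outcomes only, all T0 = 6 pre quarters
})

test_that("a donor identical to the treated region matches its predictor column after scaling", {
  ds <- toy_panel(1, 3, 6, 3,
                  covariates = matrix(c(1, 2, 3, 4), 4, 1,
                                      dimnames = list(NULL, "z1")))
  ds$outcome["d1", ] <- ds$outcome["t1", ]
  ds$covariates["d1", ] <- ds$covariates["t1", ]
  p <- build_problem(ds)
  expect_equal(unname(p$X0[, "d1"]), unname(p$X1))
})

test_that("constant predictors are excluded with a warning", {
  ds <- toy_panel(1, 3, 6, 3,
                  covariates = cbind(z1 = c(1, 2, 3, 4), zc = rep(7, 4)))
  expect_warning(p <- build_problem(ds), "zero-variance.*zc")
  expect_false("zc" %in% names(p$X1))
  expect_equal(p$dropped, "zc")
})

test_that("solve_weights handles the degenerate and interior-hull cases", {
  # single donor: simplex is a point
  p1 <- raw_problem(X1 = c(1, 2), X0 = matrix(c(3, 4), 2, 1),
                    Y1_pre = c(1, 2), Y0_pre = matrix(c(3, 4), 2, 1))
  s1 <- solve_weights(p1, c(0.3, 0.7))
  expect_equal(unname(s1$w), 1)

  # treated at the midpoint of two distinct donors
  X0 <- cbind(c(0, 0, 1), c(2, 4, 3))
  X1 <- c(1, 2, 2)
  p2 <- raw_problem(X1, X0)
  s2 <- solve_weights(p2, rep(1 / 3, 3))
  expect_equal(unname(s2$w), c(0.5, 0.5), tolerance = 1e-9)
  expect_lt(s2$objective, 1e-18)
})

test_that("QP solutions beat an exhaustive simplex grid and satisfy an interior-point cross-check", {
  skip_if_not_installed("kernlab")
  withr::with_seed(77, {
    for (rep in 1:20) {
      k <- 5; J <- 3
      X0 <- matrix(rnorm(k * J), k)
      X1 <- rnorm(k)
      V <- rexp(k); V <- V / sum(V)
      p <- raw_problem(X1, X0)
      sol <- solve_weights(p, V)
      expect_lte(sol$objective, grid_min_objective(X1, X0, V) + 1e-3)
      # independent solver route: interior-point QP from kernlab
      sv <- kernlab::ipop(c = as.numeric(-2 * t(X0 * V) %*% X1),
                          H = 2 * t(X0) %*% (V * X0) + 1e-9 * diag(J),
                          A = matrix(1, 1, J), b = 1, r = 0,
                          l = rep(0, J), u = rep(1, J),
                          margin = 5e-4, sigf = 7)
      w_ip <- kernlab::primal(sv)
      obj <- function(w) sum(V * (X1 - X0 %*% w)^2)
      expect_lte(sol$objective, obj(w_ip) + 1e-6)
    }
  })
})

test_that("every returned W and V lies on its simplex", {
  withr::with_seed(14, {
    for (rep in 1:25) {
      k <- sample(2:6, 1); J <- sample(2:8, 1)
      p <- raw_problem(rnorm(k), matrix(rnorm(k * J), k))
      V <- rexp(k); V <- V / sum(V)
      w <- solve_weights(p, V)$w
      expect_true(all(w >= -1e-8))
      expect_equal(sum(w), 1, tolerance = 1e-8)
      opt <- optimize_V(p, scm_control(n_random_starts = 2, maxit = 120))
      expect_true(all(opt$V >= -1e-8) && all(opt$W >= -1e-8))
      expect_equal(sum(opt$V), 1, tolerance = 1e-8)
      expect_equal(sum(opt$W), 1, tolerance = 1e-8)
    }
  })
})

test_that("nested V optimisation matches a 2-D grid oracle and honours k = 1", {
  p1 <- raw_problem(c(1.5), matrix(c(1, 2), 1, 2))
  expect_equal(unname(optimize_V(p1)$V), 1)

  withr::with_seed(99, {
    for (rep in 1:5) {
      X0 <- matrix(rnorm(2 * 3), 2)
      X1 <- rnorm(2)
      Y0_pre <- matrix(rnorm(4 * 3), 4)
      Y1_pre <- rnorm(4)
      p <- raw_problem(X1, X0, Y1_pre, Y0_pre)
      opt <- optimize_V(p, scm_control(n_random_starts = 4))
      grid_best <- min(vapply(0:100 / 100, function(a) {
        w <- solve_weights(p, c(a, 1 - a))$w
        sqrt(mean((Y1_pre - Y0_pre %*% w)^2))
      }, numeric(1)))
      expect_lte(opt$pre_rmspe, grid_best + 1e-3)
    }
  })
})

test_that("a duplicated treated region in the pool yields zero gaps and zero ATT", {
  withr::with_seed(6, {
    ds <- toy_panel(1, 3, 6, 3, outcome = matrix(rnorm(24), 4),
                    covariates = matrix(rnorm(4), 4, 1,
                                        dimnames = list(NULL, "z1")))
    ds$outcome["d2", ] <- ds$outcome["t1", ]
    ds$covariates["d2", ] <- ds$covariates["t1", ]
    fit <- fit_scm(ds)
    expect_lt(max(abs(fit$gaps)), 1e-7)
    expect_lt(abs(fit$att), 1e-7)
    expect_lt(fit$pre_rmspe, 1e-7)
  })
})

test_that("post-period gaps of (1, -1) with equal patient counts average to zero ATT", {
  ds <- toy_panel(1, 2, 4, 2, freq = matrix(50, 3, 4))
  # donor d1 duplicates the treated unit pre-period; treated departs post
  ds$outcome["d1", ] <- ds$outcome["t1", ]
  ds$outcome["t1", c("p3", "p4")] <- ds$outcome["t1", c("p3", "p4")] + c(1, -1)
  fit <- fit_scm(ds, predictor_spec(covariates = FALSE))
  expect_lt(fit$pre_rmspe, 1e-8)
  expect_equal(unname(fit$gaps[c("p3", "p4")]), c(1, -1), tolerance = 1e-6)
  expect_equal(fit$att, 0, tolerance = 1e-6)
})

test_that("hull scenario: exact pre fit, exact ATT, and weight recovery when unique", {
  gen <- scenario_panel("hull", seed = 13)
  fit <- fit_scm(gen$panel)
  expect_lte(fit$pre_rmspe, 1e-6)
  expect_equal(fit$att, 2, tolerance = 1e-6)

  # three affinely independent donors make the hull combination unique
  gen3 <- scenario_panel("hull", seed = 29, J_donors = 3,
                         treated_hull_weights = c(0.2, 0.5, 0.3))
  fit3 <- fit_scm(gen3$panel)
  expect_lt(max(abs(fit3$w - c(0.2, 0.5, 0.3))), 1e-4)
  expect_equal(fit3$att, 2, tolerance = 1e-6)
})

test_that("adding a constant to one period's outcomes cancels from weights and gaps", {
  gen <- scenario_panel("parallel", seed = 17)
  ds <- gen$panel
  ctl <- scm_control(fast_v = TRUE)
  f1 <- fit_scm(ds, control = ctl)
  ds2 <- ds
  ds2$outcome[, "q03"] <- ds2$outcome[, "q03"] + 5
  f2 <- fit_scm(ds2, control = ctl)
  expect_equal(f2$w, f1$w, tolerance = 1e-7)
  expect_equal(f2$gaps, f1$gaps, tolerance = 1e-7)
})

test_that("a treated region outside the donor hull reports a positive pre-RMSPE", {
  gen <- scenario_panel("parallel", seed = 23, treated_mu_shift = 10,
                        sigma_eps = 0)
  fit <- fit_scm(gen$panel, control = scm_control(fast_v = TRUE))
  expect_gt(fit$pre_rmspe, 0.1)
})

test_that("cumulative ATT weighting uses running patient totals", {
  ds <- toy_panel(1, 2, 4, 2, freq = matrix(10, 3, 4))
  ds$outcome["d1", ] <- ds$outcome["t1", ]
  ds$outcome["t1", c("p3", "p4")] <- ds$outcome["t1", c("p3", "p4")] + c(1, 3)
  pred <- predictor_spec(covariates = FALSE)
  f_per <- fit_scm(ds, pred)
  f_cum <- fit_scm(ds, pred, scm_control(att_weighting = "cumulative"))
  expect_equal(f_per$att, (1 + 3) / 2, tolerance = 1e-6)
  expect_equal(f_cum$att, (10 * 1 + 20 * 3) / 30, tolerance = 1e-6)
})
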