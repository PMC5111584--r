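test_that("the 2x2 DiD point estimate is the four-means closed form", {
  Y <- matrix(c(1, 3,   # treated: pre 1, post 3
                0, 1),  # control: pre 0, post 1
              2, 2, byrow = TRUE,
              dimnames = list(c("t1", "d1"), c("p1", "p2")))
  f <- matrix(10, 2, 2, dimnames = dimnames(Y))
  ds <- panel_dataset(Y, f, "t1",
                      stats::setNames(c("treated", "A"), c("t1", "d1")),
                      cut_period = "p1")
  res <- did_estimate(ds)
  expect_equal(res$att, (3 - 1) - (1 - 0))
})

test_that("a constant added to all post-period outcomes is absorbed by time effects", {
  withr::with_seed(10, {
    ds <- toy_panel(2, 4, 6, 3, outcome = matrix(rnorm(36), 6))
    a1 <- did_estimate(ds)$att
    ds2 <- ds
    ds2$outcome[, 4:6] <- ds2$outcome[, 4:6] + 7
    expect_equal(did_estimate(ds2)$att, a1, tolerance = 1e-10)
  })
})

test_that("the FE estimate matches the double-demeaning oracle to 1e-10", {
  withr::with_seed(55, {
    for (rep in 1:6) {
      ds <- toy_panel(3, 7, 6, 3, outcome = matrix(rnorm(60), 10))
      D <- matrix(0, 10, 6)
      D[ds$units %in% ds$treated_units, 4:6] <- 1
      expect_equal(did_estimate(ds)$att, fe_oracle(ds$outcome, D),
                   tolerance = 1e-10)
      expect_gt(did_estimate(ds)$se_cluster, 0)
    }
  })
})

test_that("treatment collinear with unit or period dummies is an error", {
  ds <- toy_panel(2, 2, 4, 2)
  all_treated <- panel_dataset(ds$outcome, ds$freq, ds$units, ds$region_of,
                               cut_period = "p2")
  expect_error(did_estimate(all_treated), "collinear")
})

test_that("matching pairs an identical donor at distance zero and preserves retained cells", {
  withr::with_seed(3, {
    ds <- toy_panel(2, 5, 6, 3, outcome = matrix(rnorm(42), 7),
                    covariates = matrix(rnorm(7), 7, 1,
                                        dimnames = list(NULL, "z1")))
    ds$outcome["d4", ] <- ds$outcome["t1", ]
    ds$covariates["d4", ] <- ds$covariates["t1", ]
    m <- match_units(ds, seed = 1)
    tab <- attr(m, "matches")
    expect_equal(tab$donor[tab$treated == "t1"], "d4")
    expect_equal(tab$distance[tab$treated == "t1"], 0, tolerance = 1e-10)
    expect_equal(m$outcome, ds$outcome[m$units, ])
  })
})

test_that("matching a panel against copies of itself gives perfect balance", {
  withr::with_seed(4, {
    nt <- 3; T <- 6
    Yt <- matrix(rnorm(nt * T), nt)
    Y <- rbind(Yt, Yt)
    rownames(Y) <- c(sprintf("t%d", 1:nt), sprintf("d%d", 1:nt))
    colnames(Y) <- sprintf("p%d", 1:T)
    f <- matrix(10, 2 * nt, T, dimnames = dimnames(Y))
    ds <- panel_dataset(Y, f, sprintf("t%d", 1:nt),
                        stats::setNames(rep(c("treated", "A"), each = nt),
                                        rownames(Y)),
                        cut_period = "p3")
    m <- match_units(ds, seed = 2)
    bal <- attr(m, "balance")
    expect_lt(max(abs(bal$smd_after)), 1e-10)
    expect_equal(max(attr(m, "matches")$distance), 0, tolerance = 1e-10)
  })
})

test_that("greedy sequential matching follows the nearest-unused-donor rule", {
  # 3 treated, 5 donors on a line; explicit processing order t1, t2, t3
  Y <- matrix(0, 8, 2)
  feat <- c(0, 1, 2, 0.1, 0.9, 2.2, 5, 6)  # t1 t2 t3 d1..d5
  Y[, 1] <- feat; Y[, 2] <- feat
  rownames(Y) <- c("t1", "t2", "t3", sprintf("d%d", 1:5))
  colnames(Y) <- c("p1", "p2")
  f <- matrix(1, 8, 2, dimnames = dimnames(Y))
  ds <- panel_dataset(Y, f, c("t1", "t2", "t3"),
                      stats::setNames(rep(c("treated", "A"), c(3, 5)),
                                      rownames(Y)),
                      cut_period = "p1")
  m <- match_units(ds, pre_outcomes = TRUE, order = c("t1", "t2", "t3"))
  tab <- attr(m, "matches")
  # greedy oracle: t1 -> d1 (0.1), t2 -> d2 (0.9), t3 -> d3 (2.2)
  expect_equal(tab$donor, c("d1", "d2", "d3"))
})

test_that("matching improves or preserves covariate balance on confounded panels", {
  withr::with_seed(19, {
    for (rep in 1:4) {
      gen <- scenario_panel("divergent", seed = 100 + rep)
      m <- match_units(gen$panel, seed = rep)
      bal <- attr(m, "balance")
      expect_lte(mean(abs(bal$smd_after)), mean(abs(bal$smd_before)) + 1e-12)
    }
  })
})

test_that("per-unit SCM reduces to the aggregate fit for a single treated unit", {
  gen <- scenario_panel("divergent", seed = 7, K1_treated = 1)
  ctl <- scm_control(fast_v = TRUE)
  per <- scm_per_unit(gen$panel, control = ctl)
  agg <- fit_scm(gen$panel, control = ctl)
  expect_equal(per$att, agg$att, tolerance = 1e-10)
  expect_equal(unname(per$gaps), unname(agg$gaps), tolerance = 1e-10)
})

test_that("per-unit SCM recovers the hull-scenario effect and equals the aggregate for identical treated units", {
  gen <- scenario_panel("hull", seed = 9)
  ctl <- scm_control(fast_v = TRUE)
  per <- scm_per_unit(gen$panel, control = ctl)
  expect_equal(per$att, 2, tolerance = 1e-6)
  agg <- fit_scm(gen$panel, control = ctl)
  expect_equal(per$att, agg$att, tolerance = 1e-6)
})

test_that("the SCM + DiD hybrid matches the per-unit aggregate under perfect fits and flags conditional inference", {
  gen <- scenario_panel("hull", seed = 15)
  ctl <- scm_control(fast_v = TRUE)
  per <- scm_per_unit(gen$panel, control = ctl)
  hyb <- scm_plus_did(gen$panel, per)
  expect_equal(hyb$att, 2, tolerance = 1e-6)
  expect_equal(hyb$att, per$att, tolerance = 1e-6)
  expect_true(hyb$conditional_on_weights)

  gen0 <- scenario_panel("hull", seed = 15, alpha = 0)
  per0 <- scm_per_unit(gen0$panel, control = ctl)
  expect_equal(scm_plus_did(gen0$panel, per0)$att, 0, tolerance = 1e-6)
})

test_that("leave-one-region-out refits once per donor region and is stable in the hull scenario", {
  gen <- scenario_panel("hull", seed = 25)
  ctl <- scm_control(fast_v = TRUE)
  loo <- leave_one_out(gen$panel, control = ctl)
  expect_equal(nrow(loo),
               length(unique(gen$panel$region_of[gen$panel$donor_units])))
  expect_lte(diff(range(loo$att)), 1e-4)

  # two donor regions -> exactly two refits
  ds2 <- toy_panel(1, 4, 6, 3)
  ds2$outcome["d1", ] <- ds2$outcome["t1", ]
  loo2 <- leave_one_out(ds2, predictor_spec(covariates = FALSE),
                        control = ctl)
  expect_equal(nrow(loo2), 2)
})

test_that("deleting a region whose donors carry no weight leaves the ATT unchanged", {
  # treated = midpoint of d1, d2 (region A); far-away donors in region B.
  # d1/d2 depart from the treated series in a non-affine pattern so the
  # exact-fit weights are unique.
  T <- 6
  e <- c(0.5, -0.3, 0.8, 0.1, -0.6, 0.4)
  Y <- rbind(t1 = 1:T,
             d1 = 1:T + e, d2 = 1:T - e,
             d3 = 1:T + c(50, 55, 47, 52, 49, 53),
             d4 = 1:T + c(60, 58, 63, 61, 59, 62))
  colnames(Y) <- sprintf("p%d", 1:T)
  f <- matrix(10, 5, T, dimnames = dimnames(Y))
  ds <- panel_dataset(Y, f, "t1",
                      stats::setNames(c("treated", "A", "A", "B", "B"),
                                      rownames(Y)),
                      cut_period = "p3")
  ctl <- scm_control(fast_v = TRUE)
  full <- fit_scm(ds, predictor_spec(covariates = FALSE), control = ctl)
  expect_lt(sum(full$w[c("d3", "d4")]), 1e-8)
  loo <- leave_one_out(ds, predictor_spec(covariates = FALSE), control = ctl)
  expect_equal(loo$att[loo$region == "B"], full$att, tolerance = 1e-8)
})

test_that("the robustness report tabulates all five estimators on one panel", {
  gen <- scenario_panel("divergent", seed = 33)
  ctl <- scm_control(fast_v = TRUE)
  rep_ <- robustness_report(gen$panel, control = ctl, B = 10, seed = 2)
  expect_setequal(rep_$table$method,
                  c("scm_aggregate", "scm_per_unit", "scm_per_unit_plus_did",
                    "did", "matching_did"))
  expect_true(all(is.finite(rep_$table$att)))
  expect_true(all(is.finite(rep_$table$p_value)))
  expect_s3_class(rep_$loo, "loo_result")
})
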