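# Shared fixture builders and independent oracles for the test suite.

# Small hand-built panel: nt treated + nd donor units, T periods, cut at T0.
# Outcomes default to unit-specific linear trends so units are distinct.
toy_panel <- function(nt = 2, nd = 4, T = 6, T0 = 3, outcome = NULL,
                      freq = NULL, covariates = NULL, regions = NULL) {
  units <- c(sprintf("t%d", seq_len(nt)), sprintf("d%d", seq_len(nd)))
  periods <- sprintf("p%d", seq_len(T))
  n <- nt + nd
  if (is.null(outcome)) {
    outcome <- outer(seq_len(n), seq_len(T), function(i, t) i + 0.1 * i * t)
  }
  dimnames(outcome) <- list(units, periods)
  if (is.null(freq)) freq <- matrix(10, n, T)
  dimnames(freq) <- list(units, periods)
  if (is.null(regions))
    regions <- c(rep("treated", nt), rep(c("A", "B"), length.out = nd))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    rownames(covariates) <- units
  }
  panel_dataset(outcome, freq, treated_units = units[seq_len(nt)],
                region_of = stats::setNames(regions, units),
                cut_period = periods[T0], covariates = covariates)
}

# Directly assemble a donor_problem for solver-level tests (bypasses the
# standardisation in build_problem so expected values are hand-checkable).
raw_problem <- function(X1, X0, Y1_pre = NULL, Y0_pre = NULL) {
  k <- length(X1); J <- ncol(X0)
  if (is.null(Y1_pre)) Y1_pre <- X1
  if (is.null(Y0_pre)) Y0_pre <- X0
  structure(list(X1 = X1, X0 = X0, scale = rep(1, k),
                 Y1_pre = Y1_pre, Y0_pre = Y0_pre,
                 Y0_post = Y0_pre, Y0 = rbind(Y0_pre, Y0_pre),
                 y_bar = c(Y1_pre, Y1_pre), f_bar = rep(1, 2 * nrow(Y0_pre)),
                 donors = sprintf("d%d", seq_len(J)), dropped = character(0),
                 cut = nrow(Y0_pre)),
            class = "donor_problem")
}

# Exhaustive simplex grids at step 1/steps for J = 2..4 donors (cached).
simplex_grid <- local({
  cache <- list()
  function(J, steps = 100) {
    key <- paste(J, steps)
    if (!is.null(cache[[key]])) return(cache[[key]])
    g <- if (J == 2) {
      a <- 0:steps
      rbind(a, steps - a)
    } else if (J == 3) {
      ab <- expand.grid(a = 0:steps, b = 0:steps)
      ab <- ab[ab$a + ab$b <= steps, ]
      rbind(ab$a, ab$b, steps - ab$a - ab$b)
    } else if (J == 4) {
      abc <- expand.grid(a = 0:steps, b = 0:steps, c = 0:steps)
      abc <- abc[abc$a + abc$b + abc$c <= steps, ]
      rbind(abc$a, abc$b, abc$c, steps - abc$a - abc$b - abc$c)
    } else stop("grid oracle supports J <= 4")
    g <- g / steps
    cache[[key]] <<- g
    g
  }
})

# Grid-search oracle for min (X1 - X0 w)' V (X1 - X0 w) over the simplex.
grid_min_objective <- function(X1, X0, V, steps = 100) {
  W <- simplex_grid(ncol(X0), steps)
  R <- sqrt(V) * (X0 %*% W - X1)   # recycles sqrt(V) down rows
  min(colSums(R^2))
}

# Double-demeaning closed-form oracle for the two-way FE DiD coefficient.
fe_oracle <- function(Y, D) {
  dd <- function(M) sweep(sweep(M, 1, rowMeans(M)), 2, colMeans(M)) + mean(M)
  Yt <- dd(Y); Dt <- dd(D)
  sum(Yt * Dt) / sum(Dt^2)
}

scenario_panel <- function(name, seed = 1, ...) {
  generate_panel(scenario_config(name, seed = seed, ...))
}
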