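#' Run configuration for the end-to-end pipeline
#'
#' Validates and normalises a configuration supplied as a list or a YAML file.
#' Every stochastic stage must carry an explicit seed; validation fails before
#' any computation otherwise.
#'
#' @param x a named list or the path to a YAML file with entries:
#'   `seed` (required); either `scenario` (one of the named generator
#'   scenarios) or `panel_csv` (+ optional `covariate_csv` and `cut_period`);
#'   optional `predictors` (list with `covariates`, `pre_outcomes`),
#'   `control` (arguments to [scm_control()]), `placebo` (list with `B`,
#'   `size`, `seed`, `rule`), `robustness` (logical, default `TRUE`),
#'   `out_dir` (default `"synthregion-run"`).
#' @return a validated `run_config` list.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x) && length(x) == 1) yaml::read_yaml(x) else x
  if (!is.list(cfg)) stop("config must be a list or a YAML file path")
  if (is.null(cfg$seed)) stop("config must declare `seed`")
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$scenario) && is.null(cfg$panel_csv))
    stop("config needs either `scenario` or `panel_csv`")
  cfg$predictors <- do.call(predictor_spec, as.list(cfg$predictors))
  ctl <- as.list(cfg$control)
  if (is.null(ctl$seed)) ctl$seed <- cfg$seed
  cfg$control <- do.call(scm_control, ctl)
  plc <- as.list(cfg$placebo)
  if (is.null(plc$B)) plc$B <- 100
  if (is.null(plc$seed)) plc$seed <- cfg$seed
  if (is.null(plc$rule)) plc$rule <- "plain"
  cfg$placebo <- plc
  if (is.null(cfg$robustness)) cfg$robustness <- TRUE
  if (is.null(cfg$robustness_B)) cfg$robustness_B <- 0
  if (is.null(cfg$out_dir)) cfg$out_dir <- "synthregion-run"
  if (is.null(cfg$figures)) cfg$figures <- TRUE
  class(cfg) <- "run_config"
  cfg
}

fit_to_list <- function(fit) {
  list(att = fit$att, pre_rmspe = fit$pre_rmspe,
       w = as.list(fit$w), v = as.list(fit$v),
       gaps = as.list(fit$gaps), synthetic = as.list(fit$synthetic),
       y_bar = as.list(stats::setNames(fit$y_bar, fit$periods)),
       att_weights = as.list(fit$att_weights),
       periods = fit$periods, cut = fit$cut, objective = fit$objective)
}

placebo_to_list <- function(plc) {
  list(observed_att = plc$observed_att, p_two_sided = plc$p_two_sided,
       rule = plc$rule, B = plc$B, n_failed = plc$n_failed,
       placebo_size = plc$placebo_size, seed = plc$seed,
       placebo_atts = plc$placebo_atts,
       observed_gaps = as.list(plc$observed_gaps),
       placebo_gaps = apply(plc$placebo_gaps, 1, as.list, simplify = FALSE),
       periods = plc$periods, cut = plc$cut)
}

write_json_artifact <- function(x, path)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

#' Run the full analysis pipeline
#'
#' Generates (or reads) the panel, fits the aggregate synthetic control, runs
#' the placebo test, optionally the robustness battery, writes the JSON
#' artifacts (`fit.json`, `placebo.json`, `report.json`), the resolved
#' configuration, a log with package versions, and the four standard figures.
#' Identical configurations (including seeds) give identical JSON payloads.
#'
#' @param cfg a [run_config()] (or anything it accepts).
#' @return the run directory path, invisibly; the parsed artifacts are
#'   attached as `attr(, "results")`.
#' @export
run_pipeline <- function(cfg) {
  cfg <- run_config(cfg)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(cfg$out_dir, "log.txt")
  logline <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "),
                               ..., "\n", sep = "", file = logf, append = TRUE)
  cat("", file = logf)
  logline("synthregion ", as.character(utils::packageVersion("synthregion")),
          " | R ", paste(R.version$major, R.version$minor, sep = "."))

  stage <- "data"
  res <- tryCatch({
    if (!is.null(cfg$scenario)) {
      gen <- generate_panel(scenario_config(cfg$scenario, seed = cfg$seed))
      ds <- gen$panel
      write_panel(ds, file.path(cfg$out_dir, "panel.csv"),
                  file.path(cfg$out_dir, "covariates.csv"))
      write_json_artifact(list(alpha = gen$truth$alpha,
                               hull_weights = gen$truth$hull_weights),
                          file.path(cfg$out_dir, "ground_truth.json"))
      logline("generated scenario '", cfg$scenario, "' panel: ",
              length(ds$units), " units x ", length(ds$periods), " periods")
    } else {
      ds <- read_panel(cfg$panel_csv, cfg$covariate_csv, cfg$cut_period)
      logline("read panel from ", cfg$panel_csv)
    }

    stage <- "scm_fit"
    fit <- fit_scm(ds, cfg$predictors, cfg$control)
    write_json_artifact(fit_to_list(fit), file.path(cfg$out_dir, "fit.json"))
    logline("SCM fit: ATT = ", format(fit$att), ", pre-RMSPE = ",
            format(fit$pre_rmspe))

    stage <- "placebo"
    plc <- run_placebos(ds, fit, B = cfg$placebo$B, size = cfg$placebo$size,
                        seed = cfg$placebo$seed, predictors = cfg$predictors,
                        control = cfg$control, rule = cfg$placebo$rule)
    write_json_artifact(placebo_to_list(plc),
                        file.path(cfg$out_dir, "placebo.json"))
    logline("placebo test: p = ", format(plc$p_two_sided), " (B = ",
            plc$B, ")")

    rep <- NULL
    if (isTRUE(cfg$robustness)) {
      stage <- "robustness"
      rep <- robustness_report(ds, cfg$predictors, cfg$control,
                               B = cfg$robustness_B, seed = cfg$seed)
      write_json_artifact(
        list(table = rep$table, leave_one_out = rep$loo,
             loo_att_range = attr(rep$loo, "range")),
        file.path(cfg$out_dir, "report.json"))
      utils::write.csv(rep$table,
                       file.path(cfg$out_dir, "report.csv"),
                       row.names = FALSE)
      logline("robustness: ",
              paste(rep$table$method, round(rep$table$att, 4),
                    sep = "=", collapse = ", "))
    }

    stage <- "figures"
    if (isTRUE(cfg$figures)) {
      save_fig <- function(plot, name)
        ggplot2::ggsave(file.path(cfg$out_dir, name), plot,
                        width = 7, height = 5, dpi = 150)
      save_fig(plot_trajectories(file.path(cfg$out_dir, "fit.json")),
               "trajectories.png")
      save_fig(plot_gaps(file.path(cfg$out_dir, "fit.json")), "gaps.png")
      save_fig(plot_placebo_gaps(file.path(cfg$out_dir, "placebo.json")),
               "placebo_gaps.png")
      save_fig(plot_placebo_hist(file.path(cfg$out_dir, "placebo.json")),
               "placebo_hist.png")
    }

    resolved <- cfg
    class(resolved) <- NULL
    resolved$predictors <- unclass(resolved$predictors)
    resolved$control <- unclass(resolved$control)
    yaml::write_yaml(resolved, file.path(cfg$out_dir, "config_resolved.yaml"))
    list(panel = ds, fit = fit, placebo = plc, robustness = rep)
  }, error = function(e) {
    logline("FAILED at stage '", stage, "': ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  out <- cfg$out_dir
  attr(out, "results") <- res
  invisible(out)
}

read_artifact <- function(x, cls) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  x
}

#' Treated vs synthetic trajectory plot
#'
#' @param fit an `scm_fit` or the path to a `fit.json` artifact.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(fit) {
  f <- read_artifact(fit)
  df <- data.frame(
    period = factor(rep(f$periods, 2), levels = f$periods),
    mortality = c(unlist(f$y_bar), unlist(f$synthetic)),
    series = rep(c("treated region", "synthetic control"),
                 each = length(f$periods)))
  ggplot2::ggplot(df, ggplot2::aes(.data$period, .data$mortality,
                                   group = .data$series,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = f$cut + 0.5, linetype = 3) +
    ggplot2::labs(x = "period", y = "risk-adjusted mortality (% points)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Gap (treated minus synthetic) plot
#'
#' @param fit an `scm_fit` or the path to a `fit.json` artifact.
#' @return a ggplot object.
#' @export
plot_gaps <- function(fit) {
  f <- read_artifact(fit)
  df <- data.frame(period = factor(f$periods, levels = f$periods),
                   gap = unlist(f$gaps))
  ggplot2::ggplot(df, ggplot2::aes(.data$period, .data$gap, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = f$cut + 0.5, linetype = 3) +
    ggplot2::labs(x = "period", y = "gap (% points)") +
    ggplot2::theme_minimal()
}

#' Placebo spaghetti plot: observed gap against all placebo gaps
#'
#' @param plc a `placebo_result` or the path to a `placebo.json` artifact.
#' @return a ggplot object.
#' @export
plot_placebo_gaps <- function(plc) {
  p <- read_artifact(plc)
  gaps <- p$placebo_gaps
  if (is.list(gaps)) gaps <- do.call(rbind, lapply(gaps, unlist))
  Tt <- length(p$periods)
  df <- data.frame(
    period = factor(rep(p$periods, times = nrow(gaps)), levels = p$periods),
    gap = as.vector(t(gaps)),
    draw = rep(seq_len(nrow(gaps)), each = Tt))
  obs <- data.frame(period = factor(p$periods, levels = p$periods),
                    gap = unlist(p$observed_gaps))
  ggplot2::ggplot(df, ggplot2::aes(.data$period, .data$gap,
                                   group = .data$draw)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3) +
    ggplot2::geom_line(data = obs, ggplot2::aes(group = 1), colour = "black",
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = p$cut + 0.5, linetype = 3) +
    ggplot2::labs(x = "period", y = "gap (% points)") +
    ggplot2::theme_minimal()
}

#' Placebo ATT histogram with +/- observed ATT reference lines
#'
#' @param plc a `placebo_result` or the path to a `placebo.json` artifact.
#' @return a ggplot object.
#' @export
plot_placebo_hist <- function(plc) {
  p <- read_artifact(plc)
  df <- data.frame(att = unlist(p$placebo_atts))
  ggplot2::ggplot(df, ggplot2::aes(.data$att)) +
    ggplot2::geom_histogram(bins = 25, fill = "grey75", colour = "grey30") +
    ggplot2::geom_vline(xintercept = c(-1, 1) * abs(p$observed_att),
                        linetype = 2) +
    ggplot2::labs(x = "placebo ATT (% points)", y = "count") +
    ggplot2::theme_minimal()
}
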