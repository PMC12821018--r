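#' Run configuration for batch processing
#'
#' Central defaults for the batch entry points. All thresholds trace to
#' the analysis protocol: 10% setpoint tolerance, 90-100% force window for
#' the stiffness slope, one-hour postmortem bins starting at 1.5 h,
#' reference temperature 38 degrees C, significance level 0.05.
#'
#' @param model Contact model for fitting, `"hertz"` or `"sneddon"`.
#' @param qc_tolerance Relative setpoint deviation tolerance.
#' @param baseline_fraction First-pass baseline fraction.
#' @param stiffness_window Force-fraction window for the stiffness slope.
#' @param bin_start,bin_width Postmortem binning (h).
#' @param t_ref Reference temperature (degree C).
#' @param alpha Significance level for the model comparison.
#' @param seed Integer seed for simulation commands.
#' @param out_dir Output directory for batch commands.
#' @return A `run_config` list.
#' @export
run_config <- function(model = "hertz", qc_tolerance = 0.10,
                       baseline_fraction = 0.3,
                       stiffness_window = c(0.9, 1), bin_start = 1.5,
                       bin_width = 1, t_ref = 38, alpha = 0.05,
                       seed = 1L, out_dir = ".") {
  cfg <- as.list(environment())
  stopifnot(model %in% c("hertz", "sneddon"), qc_tolerance > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @return `read_run_config()`: the configuration stored at `path`;
#'   `write_run_config()`: `path`, invisibly. A config round-trips through
#'   its file representation losslessly.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Batch-fit a directory of curve files
#'
#' Reads every curve file, runs the per-curve pipeline and writes
#' `results.csv` (one row per curve, QC verdicts included) plus a
#' `provenance.json` run record (config, seed, counts by QC reason).
#' Excluded curves are data, not errors: the command succeeds as long as
#' the inputs are readable.
#'
#' @param input Directory of curve files or character vector of paths.
#' @param config A [run_config()].
#' @param quiet Suppress the run log (messages to stderr).
#' @return The per-curve results tibble, invisibly written to
#'   `file.path(config$out_dir, "results.csv")`.
#' @export
cmd_fit <- function(input, config = run_config(), quiet = FALSE) {
  res <- fit_curves(input, model = config$model,
                    qc_tolerance = config$qc_tolerance,
                    baseline_fraction = config$baseline_fraction,
                    stiffness_window = config$stiffness_window)
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
  readr::write_csv(res, file.path(config$out_dir, "results.csv"))
  counts <- c(read = nrow(res), kept = sum(res$keep),
              table(unlist(strsplit(res$reasons[res$reasons != ""], ","))))
  write_provenance(config, file.path(config$out_dir, "provenance.json"),
                   counts = as.list(counts))
  if (!quiet) {
    message(sprintf("fit: %d curves read, %d kept, %d excluded",
                    nrow(res), sum(res$keep), sum(!res$keep)))
  }
  invisible(res)
}

#' Summarise batch results into maps, bins and regressions
#'
#' Joins per-curve results to the manifest, builds per-map compartment
#' summaries, and, where the relevant axis varies, a one-hour-binned
#' postmortem series and a temperature regression report (linear vs
#' horizontal per compartment and for the gray-to-white ratio, with
#' relative slopes at `t_ref`).
#'
#' @param results Per-curve tibble from [cmd_fit()]/[fit_curves()], or a
#'   path to `results.csv`.
#' @param manifest Manifest tibble or path to `manifest.csv` (columns
#'   `x_um`, `y_um`, `label`, and `map_id` grouping curves into maps).
#' @param config A [run_config()].
#' @param write Write `summaries.csv` (plus `binned.csv`/`regression.csv`
#'   when computed) under `config$out_dir`.
#' @return A list: `summaries`, `binned` (or `NULL`), `regression` (or
#'   `NULL`).
#' @export
cmd_summarize <- function(results, manifest, config = run_config(),
                          write = TRUE) {
  if (is.character(results)) results <- readr::read_csv(results, show_col_types = FALSE)
  if (is.character(manifest)) manifest <- readr::read_csv(manifest, show_col_types = FALSE)
  if (!"map_id" %in% names(manifest)) manifest$map_id <- "map001"
  if (!"curve_file" %in% names(results) ||
      !"curve_file" %in% names(manifest)) {
    results$map_id <- "map001"
  } else {
    results <- dplyr::left_join(
      results, manifest[, c("curve_file", "map_id")], by = "curve_file")
  }
  summaries <- results |>
    dplyr::group_split(.data$map_id) |>
    purrr::map_dfr(function(res) {
      mid <- res$map_id[1]
      man <- manifest[manifest$map_id == mid, ]
      map <- as_elasticity_map(res, man)
      out <- summarize_map(map)
      out$map_id <- mid
      out
    })
  binned <- NULL
  if (length(unique(round(summaries$t_mean_h, 6))) > 1) {
    binned <- bin_timeseries(summaries, time = "t_mean_h", value = "ratio",
                             bin_start = config$bin_start,
                             bin_width = config$bin_width)
  }
  regression <- NULL
  temps <- summaries$temp_mean_c
  if (sum(is.finite(temps)) >= 3 && diff(range(temps, na.rm = TRUE)) > 0) {
    regression <- regression_report(summaries, t_ref = config$t_ref,
                                    alpha = config$alpha)
  }
  if (write) {
    if (!dir.exists(config$out_dir)) dir.create(config$out_dir, recursive = TRUE)
    readr::write_csv(summaries, file.path(config$out_dir, "summaries.csv"))
    if (!is.null(binned)) {
      readr::write_csv(binned, file.path(config$out_dir, "binned.csv"))
    }
    if (!is.null(regression)) {
      readr::write_csv(regression, file.path(config$out_dir, "regression.csv"))
    }
  }
  list(summaries = summaries, binned = binned, regression = regression)
}

#' Temperature regression report over map summaries
#'
#' One row per response (gray, white, ratio): linear-vs-horizontal model
#' comparison of the per-map medians against temperature, with the
#' relative slope at `t_ref` for responses where the linear model is
#' preferred. Gray and white regress on their compartment's median
#' temperature; the ratio regresses on the mean of the two.
#'
#' @param summaries Tibble of [summarize_map()] rows.
#' @param t_ref Reference temperature (degree C).
#' @param alpha Significance level.
#' @return A tibble mirroring a regression table: `response`, `slope`,
#'   `intercept`, `constant`, `f_statistic`, `p_value`, `adj_r_squared`,
#'   `preferred`, `predicted_at_ref`, `relative_slope_pct`.
#' @export
regression_report <- function(summaries, t_ref = 38, alpha = 0.05) {
  specs <- list(
    gray = c("temp_gray_c", "median_K_gray"),
    white = c("temp_white_c", "median_K_white"),
    ratio = c("temp_mean_c", "ratio"))
  purrr::imap_dfr(specs, function(cols, nm) {
    fit <- fit_linear_vs_constant(summaries, cols[1], cols[2], alpha = alpha)
    g <- glance(fit)
    rs <- tryCatch(relative_slope(fit, t_ref = t_ref), error = function(e) {
      tibble::tibble(predicted_at_ref = NA_real_, relative_slope_pct = NA_real_)
    })
    tibble::tibble(response = nm, slope = g$slope, intercept = g$intercept,
                   constant = g$constant, f_statistic = g$f_statistic,
                   p_value = g$p_value, adj_r_squared = g$adj_r_squared,
                   preferred = g$preferred,
                   predicted_at_ref = rs$predicted_at_ref,
                   relative_slope_pct = rs$relative_slope_pct)
  })
}

#' Simulate an experiment directory
#'
#' Thin wrapper over [make_phantom()] + [simulate_experiment()] writing a
#' ready-to-fit experiment directory (curve files, `manifest.csv`,
#' `truth.csv`, `provenance.json`).
#'
#' @param preset Phantom preset.
#' @param protocol A [protocol()].
#' @param dir Output directory.
#' @param seed Master seed (required).
#' @return The [simulate_experiment()] result, invisibly.
#' @export
cmd_simulate <- function(preset = "transverse", protocol = protocol(),
                         dir, seed) {
  if (missing(seed)) stop("`seed` is required for simulation", call. = FALSE)
  phantom <- make_phantom(preset)
  out <- simulate_experiment(phantom, protocol, seed = seed, dir = dir)
  write_provenance(list(preset = preset, seed = seed),
                   file.path(dir, "provenance.json"),
                   counts = list(curves = length(out$curves)))
  invisible(out)
}

write_provenance <- function(config, path, counts = list()) {
  rec <- list(
    package = "forcemap",
    version = as.character(utils::packageVersion("forcemap")),
    config = lapply(unclass(config), function(x)
      if (is.function(x) || inherits(x, "noise_model")) unclass(x) else x),
    counts = counts)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
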