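#' Build a measurement grid over a sample outline
#'
#' Regular square lattice at pitch `resolution`, clipped to the interior
#' of a simple polygon. Lattice points sit at cell centres
#' (`xmin + (i - 1/2) * resolution`), so a 1 mm square at 200 um pitch
#' yields exactly 5 x 5 positions; a point exactly on the outline counts
#' as interior. Ordering is row-major with x (mediolateral) as the fast
#' axis, so acquisition order is deterministic.
#'
#' @param outline Two-column matrix or data frame of polygon vertices (m).
#' @param resolution Grid pitch (m), `> 0`.
#' @return A tibble `x_m`, `y_m` of retained lattice positions.
#' @export
build_grid <- function(outline, resolution) {
  outline <- as.matrix(outline)
  if (ncol(outline) != 2 || nrow(outline) < 3 ||
      nrow(unique(outline)) < 3) {
    stop("`outline` must be a simple polygon with >= 3 distinct vertices",
         call. = FALSE)
  }
  if (diff(range(outline[, 1])) == 0 || diff(range(outline[, 2])) == 0) {
    stop("`outline` is degenerate (zero extent)", call. = FALSE)
  }
  check_positive(resolution, "resolution")
  rng_x <- range(outline[, 1]); rng_y <- range(outline[, 2])
  axis_pts <- function(rng) {
    start <- rng[1] + resolution / 2
    if (start > rng[2]) numeric(0) else seq(start, rng[2], by = resolution)
  }
  xs <- axis_pts(rng_x)
  ys <- axis_pts(rng_y)
  if (length(xs) == 0 || length(ys) == 0) {
    return(tibble::tibble(x_m = numeric(), y_m = numeric()))
  }
  grid <- tidyr::expand_grid(y_m = ys, x_m = xs)[, c("x_m", "y_m")]
  keep <- in_poly(grid$x_m, grid$y_m, outline)
  grid[keep, ]
}

#' Average repeated measurements at one position
#'
#' Arithmetic mean of K over the QC-passing results at a position;
#' excluded results never contribute. With no passing result the value is
#' missing with a reason.
#'
#' @param results Tibble of per-curve rows (as from [fit_curves()]) at one
#'   position, with columns `K_pa` and `keep`.
#' @return A one-row tibble `K_pa`, `n_used`, `n_total`, `reason`.
#' @export
aggregate_repeats <- function(results) {
  ok <- results$keep & is.finite(results$K_pa)
  if (!any(ok)) {
    return(tibble::tibble(K_pa = NA_real_, n_used = 0L,
                          n_total = nrow(results),
                          reason = "all_excluded"))
  }
  tibble::tibble(K_pa = mean(results$K_pa[ok]), n_used = sum(ok),
                 n_total = nrow(results), reason = NA_character_)
}

#' Assemble an elasticity map from per-curve results and a manifest
#'
#' Joins fit results to the compartment-label manifest by exact position
#' key (x/y in um, rounded to 1 nm), averages repeated measurements per
#' position with [aggregate_repeats()], and drops QC-excluded entries.
#' Positions present in one table but not the other are an error: grids
#' are expected to repeat exactly across remeasurements.
#'
#' @param results Per-curve tibble from [fit_curves()] (columns `x_m`,
#'   `y_m` or `x_um`, `y_um`, `K_pa`, `keep`, metadata).
#' @param manifest Tibble with `x_um`, `y_um`, `label` in
#'   `c("gray", "white", "excluded")` (and optional `map_id`).
#' @return An `elasticity_map` tibble: one row per retained position with
#'   `x_um`, `y_um`, `label`, `K_pa`, `n_used`, `postmortem_h`,
#'   `temperature_c`.
#' @export
as_elasticity_map <- function(results, manifest) {
  if (!"x_um" %in% names(results)) {
    results <- dplyr::mutate(results, x_um = .data$x_m * 1e6,
                             y_um = .data$y_m * 1e6)
  }
  keyfun <- function(x, y) paste(round(x, 3), round(y, 3))
  results$pos_key <- keyfun(results$x_um, results$y_um)
  manifest$pos_key <- keyfun(manifest$x_um, manifest$y_um)
  missing_lab <- setdiff(results$pos_key, manifest$pos_key)
  missing_res <- setdiff(manifest$pos_key, results$pos_key)
  if (length(missing_lab) > 0 || length(missing_res) > 0) {
    stop("position mismatch between results and manifest; offending keys: ",
         paste(utils::head(c(missing_lab, missing_res), 5), collapse = "; "),
         call. = FALSE)
  }
  agg <- results |>
    dplyr::group_by(.data$pos_key) |>
    dplyr::group_modify(function(df, key) {
      out <- aggregate_repeats(df)
      out$x_um <- df$x_um[1]; out$y_um <- df$y_um[1]
      out$postmortem_h <- stats::median(df$postmortem_h)
      out$temperature_c <- stats::median(df$temperature_c)
      out
    }) |>
    dplyr::ungroup()
  lab <- dplyr::distinct(manifest[, c("pos_key", "label")])
  out <- dplyr::inner_join(agg, lab, by = "pos_key") |>
    dplyr::filter(.data$n_used > 0) |>
    dplyr::select("x_um", "y_um", "label", "K_pa", "n_used",
                  "postmortem_h", "temperature_c")
  class(out) <- c("elasticity_map", class(out))
  out
}

#' Per-map compartment summary
#'
#' Medians of K per compartment over the retained entries of one map, the
#' gray-to-white ratio of those medians, counts, and the time/temperature
#' stamps used downstream: the median postmortem time (and temperature)
#' per compartment, and the mean of the two compartment medians, which is
#' the x value paired with the ratio. Entries labelled `"excluded"` never
#' contribute. With an empty compartment its median and the ratio are
#' reported missing.
#'
#' The ratio is always the ratio of the two per-map medians, never a
#' median of pointwise ratios.
#'
#' @param map An `elasticity_map` (or any tibble with `label`, `K_pa`,
#'   `postmortem_h`, `temperature_c`).
#' @return A one-row tibble: `median_K_gray`, `median_K_white`, `ratio`,
#'   `n_gray`, `n_white`, `t_gray_h`, `t_white_h`, `t_mean_h`,
#'   `temp_gray_c`, `temp_white_c`, `temp_mean_c`.
#' @export
summarize_map <- function(map) {
  used <- map[map$label %in% c("gray", "white"), ]
  if (nrow(used) == 0) stop("map has no retained gray/white entries",
                            call. = FALSE)
  med <- function(lab, col) {
    v <- used[[col]][used$label == lab]
    if (length(v) == 0) NA_real_ else stats::median(v)
  }
  m_g <- med("gray", "K_pa"); m_w <- med("white", "K_pa")
  t_g <- med("gray", "postmortem_h"); t_w <- med("white", "postmortem_h")
  c_g <- med("gray", "temperature_c"); c_w <- med("white", "temperature_c")
  tibble::tibble(
    median_K_gray = m_g, median_K_white = m_w,
    ratio = if (is.na(m_g) || is.na(m_w)) NA_real_ else m_g / m_w,
    n_gray = sum(used$label == "gray"), n_white = sum(used$label == "white"),
    t_gray_h = t_g, t_white_h = t_w, t_mean_h = mean(c(t_g, t_w)),
    temp_gray_c = c_g, temp_white_c = c_w, temp_mean_c = mean(c(c_g, c_w)))
}

#' Bin a postmortem time series into one-hour bins
#'
#' Assigns records to half-open one-hour bins starting at 1:30 h
#' postmortem (`[1.5 + i, 2.5 + i)` by default) and reports per-bin mean,
#' SD (n-1 denominator; missing for singleton bins) and count. Records
#' earlier than the first edge land in a flagged underflow bin rather than
#' being dropped, so counts are conserved.
#'
#' @param data Tibble of records.
#' @param time,value Column names (strings) holding the time (h) and the
#'   binned quantity.
#' @param bin_start First bin edge (h), default 1.5.
#' @param bin_width Bin width (h), default 1.
#' @return A tibble `bin_start_h`, `bin_mid_h`, `mean`, `sd`, `n`,
#'   `underflow`.
#' @export
bin_timeseries <- function(data, time = "t_mean_h", value = "ratio",
                           bin_start = 1.5, bin_width = 1) {
  tt <- data[[time]]; vv <- data[[value]]
  if (is.null(tt) || is.null(vv)) {
    stop("`time`/`value` columns not found", call. = FALSE)
  }
  if (any(!is.finite(tt))) {
    stop("every record needs a finite time to be binned", call. = FALSE)
  }
  idx <- floor((tt - bin_start) / bin_width)
  under <- idx < 0
  idx[under] <- -1L
  tibble::tibble(idx = idx, v = vv, under = under) |>
    dplyr::group_by(.data$idx) |>
    dplyr::summarise(
      bin_start_h = if (.data$idx[1] < 0) -Inf else
        bin_start + .data$idx[1] * bin_width,
      bin_mid_h = bin_start_h + bin_width / 2,
      mean = mean(.data$v),
      sd = if (dplyr::n() >= 2) stats::sd(.data$v) else NA_real_,
      n = dplyr::n(),
      underflow = .data$under[1],
      .groups = "drop") |>
    dplyr::arrange(.data$bin_start_h) |>
    dplyr::select(-"idx")
}

#' Compare elasticity changes between two map halves
#'
#' For a continuously remeasured half versus a sparsely measured control
#' half: computes, per half and compartment, the relative change of the
#' median K from the first to the last timepoint, and the ratio of those
#' changes between halves (1 = no measurement-induced effect).
#'
#' @param summaries Tibble of per-map [summarize_map()] rows with added
#'   columns `half` (identifier) and `timepoint_h`.
#' @return A list: `per_half` tibble (`half`, `change_gray`,
#'   `change_white`, first/last times) and `between` tibble with the
#'   gray/white between-half change ratios.
#' @export
compare_halves <- function(summaries) {
  halves <- unique(summaries$half)
  if (length(halves) != 2) {
    stop("exactly two halves are required", call. = FALSE)
  }
  per_half <- purrr::map_dfr(halves, function(h) {
    s <- summaries[summaries$half == h, ]
    s <- s[order(s$timepoint_h), ]
    if (nrow(s) < 2) {
      stop(sprintf("half '%s' lacks first and last timepoints", h),
           call. = FALSE)
    }
    tibble::tibble(
      half = h, t_first_h = s$timepoint_h[1],
      t_last_h = s$timepoint_h[nrow(s)],
      change_gray = s$median_K_gray[nrow(s)] / s$median_K_gray[1],
      change_white = s$median_K_white[nrow(s)] / s$median_K_white[1])
  })
  between <- tibble::tibble(
    change_ratio_gray = per_half$change_gray[1] / per_half$change_gray[2],
    change_ratio_white = per_half$change_white[1] / per_half$change_white[2])
  list(per_half = per_half, between = between)
}
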