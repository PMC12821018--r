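#' Fit the pre-contact baseline of a force curve
#'
#' Least-squares line (offset + tilt) fitted to the early, out-of-contact
#' part of the extend segment. The window is the first `precontact_fraction`
#' of the extend z span, optionally capped at `z_max` (used when a
#' provisional contact point is known, so the window never reaches into
#' contact). The fitted line `F(z) = offset + tilt * (z - z0)` (with `z0`
#' the first extend height) is subtracted by [apply_baseline()] before any
#' contact fitting.
#'
#' @param curve A calibrated [force_curve()].
#' @param precontact_fraction Fraction of the (capped) extend z span used,
#'   in `(0, 0.9]`; default 0.5.
#' @param z_max Optional height cap (m): only samples with `height_m <
#'   z_max` are considered part of the pre-contact region.
#' @return A list `baseline` with `offset` (N), `tilt` (N/m), `z0` (m) and
#'   `n` (samples used).
#' @export
fit_baseline <- function(curve, precontact_fraction = 0.5, z_max = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  if (!curve$calibrated) curve <- calibrate(curve)
  if (precontact_fraction <= 0 || precontact_fraction > 0.9) {
    stop("`precontact_fraction` must be in (0, 0.9]", call. = FALSE)
  }
  ext <- curve$data[curve$data$segment == "extend", ]
  z <- ext$height_m
  z0 <- z[1]
  hi <- if (is.null(z_max)) max(z) else z_max
  span <- hi - z0
  sel <- z <= z0 + precontact_fraction * span
  if (sum(sel) < 10) {
    stop(sprintf(
      "baseline window holds %d samples (< 10); no usable pre-contact region",
      sum(sel)), call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, z[sel] - z0), ext$force_n[sel])
  list(offset = unname(fit$coefficients[1]),
       tilt = unname(fit$coefficients[2]), z0 = z0, n = sum(sel))
}

#' @rdname fit_baseline
#' @param baseline A baseline list from [fit_baseline()].
#' @return `apply_baseline()`: the curve with the baseline line subtracted
#'   from `force_n` (and `deflection_m` updated to match).
#' @export
apply_baseline <- function(curve, baseline) {
  stopifnot(inherits(curve, "force_curve"))
  if (!curve$calibrated) curve <- calibrate(curve)
  line <- baseline$offset + baseline$tilt * (curve$data$height_m - baseline$z0)
  curve$data$force_n <- curve$data$force_n - line
  curve$data$deflection_m <- curve$data$force_n / curve$spring_constant
  curve
}

#' Locate the contact point of a force curve
#'
#' Grid search over candidate contact points on the sampled heights of the
#' (baseline-corrected) extend segment. Each candidate `z_c` is scored by a
#' least-squares fit of the chosen contact model to all samples beyond it,
#' with the indentation computed as in [compute_indentation()]; the score is
#' the residual sum of squares per fitted point, which prevents bias toward
#' late candidates that leave few samples in the fit. The search is
#' coarse-to-fine (coarse candidate lattice, then every sample around the
#' coarse minimum) and the final `z_c` is refined by parabolic interpolation
#' of the RSS profile around its minimum, so resolution is not limited to
#' the sampling pitch.
#'
#' Candidates are restricted to heights where the corrected force is below
#' `max_force_fraction` of the maximum exerted force: a contact point sits
#' near zero force by definition, and without this restriction a candidate
#' deep inside the contact region can, by fitting only the last few
#' samples, reach a per-point RSS below the noise floor by chance.
#'
#' @param curve A calibrated, baseline-corrected [force_curve()].
#' @param model Contact model used for scoring, `"hertz"` or `"sneddon"`.
#' @param n_coarse Number of coarse candidates (default 160).
#' @param min_fit_points Minimum samples past contact for a candidate.
#' @param max_force_fraction Candidate contact points are only considered
#'   where force is below this fraction of the maximum (default 0.3).
#' @return A list with `z_c` (m) and `fit`, the winning [fit_modulus()]
#'   result at the refined contact point.
#' @export
find_contact_point <- function(curve, model = c("hertz", "sneddon"),
                               n_coarse = 160L, min_fit_points = 20L,
                               max_force_fraction = 0.3) {
  stopifnot(inherits(curve, "force_curve"))
  model <- match.arg(model)
  if (!curve$calibrated) {
    stop("curve must be calibrated (and baseline-corrected) first",
         call. = FALSE)
  }
  ext <- curve$data[curve$data$segment == "extend", ]
  n <- nrow(ext)
  if (n < 50) stop("extend segment has < 50 samples", call. = FALSE)
  z <- ext$height_m
  f <- ext$force_n
  R <- curve$bead_radius
  k_c <- curve$spring_constant
  # candidate range: leave room for a baseline before and a fit after,
  # and stay below the force cap (see above)
  i_lo <- 10L
  i_hi <- n - max(min_fit_points, 20L)
  if (i_hi <= i_lo) stop("too few samples to search for contact", call. = FALSE)
  f_cap <- max_force_fraction * max(f)
  over <- which(f > f_cap)
  # force rises monotonically past contact up to noise: cap at first excess
  if (length(over) > 0) i_hi <- min(i_hi, over[1] - 1L)
  if (i_hi <= i_lo) {
    stop("contact not found: force never stays below the candidate force cap",
         call. = FALSE)
  }
  shape <- contact_shape_fun(R, model, depth_max = max(z) - min(z))

  score_at <- function(z_c, f_c) {
    j <- which(z > z_c)
    if (length(j) < min_fit_points) return(Inf)
    delta <- (z[j] - z_c) - (f[j] - f_c) / k_c
    keep <- delta >= 0
    if (sum(keep) < min_fit_points) return(Inf)
    g <- shape(delta[keep])
    ff <- f[j][keep] - f_c
    denom <- sum(g * g)
    if (denom <= 0) return(Inf)
    K <- sum(ff * g) / denom
    if (!is.finite(K) || K <= 0) return(Inf)
    mean((ff - K * g)^2)
  }

  coarse <- unique(round(seq(i_lo, i_hi, length.out = min(n_coarse, i_hi - i_lo + 1L))))
  rss_c <- vapply(coarse, function(i) score_at(z[i], f[i]), numeric(1))
  if (all(!is.finite(rss_c))) {
    stop("contact not found: no candidate admits a positive-modulus fit",
         call. = FALSE)
  }
  ib <- coarse[which.min(rss_c)]
  step <- max(1L, diff(coarse[1:2]))
  fine <- seq(max(i_lo, ib - step), min(i_hi, ib + step))
  rss_f <- vapply(fine, function(i) score_at(z[i], f[i]), numeric(1))
  k <- which.min(rss_f)
  at_lo <- k == 1L && fine[1] == i_lo
  at_hi <- k == length(rss_f) && fine[k] >= n - max(min_fit_points, 20L)
  if (at_lo || at_hi) {
    stop("contact not found: RSS profile has no interior minimum",
         call. = FALSE)
  }
  # parabolic interpolation of log-RSS through the minimum and neighbours
  z_c <- z[fine[k]]
  if (k > 1L && k < length(rss_f) && all(is.finite(rss_f[(k - 1):(k + 1)]))) {
    zz <- z[fine[(k - 1):(k + 1)]]
    yy <- log(rss_f[(k - 1):(k + 1)])
    d21 <- (yy[2] - yy[1]) / (zz[2] - zz[1])
    d32 <- (yy[3] - yy[2]) / (zz[3] - zz[2])
    curv <- (d32 - d21) / (zz[3] - zz[1])
    if (is.finite(curv) && curv > 0) {
      z_v <- (zz[1] + zz[2]) / 2 - d21 / (2 * curv)
      if (z_v >= zz[1] && z_v <= zz[3]) z_c <- z_v
    }
  }
  ind <- compute_indentation(curve, z_c)
  fit <- fit_modulus(ind, model = model, warn_regime = FALSE)
  list(z_c = z_c, fit = fit)
}

#' Convert a force curve to a force-indentation curve
#'
#' Standard AFM kinematics past contact: the indentation is the piezo
#' travel beyond the contact point minus the additional cantilever
#' deflection, `delta = (z - z_c) - (d - d_c)`. Pre-contact samples are
#' retained with `in_fit = FALSE` for diagnostics; samples past contact
#' with numerically negative indentation (noise) are likewise excluded
#' from fitting.
#'
#' @param curve A calibrated, baseline-corrected [force_curve()].
#' @param z_c Contact point height (m); must lie within the extend range.
#' @return An `indentation_curve`: list with `data` (tibble `delta_m`,
#'   `force_n`, `time_s`, `in_fit`), `z_c`, `t_delta` (indentation duration,
#'   s), plus probe and setpoint metadata carried over.
#' @export
compute_indentation <- function(curve, z_c) {
  stopifnot(inherits(curve, "force_curve"))
  if (!curve$calibrated) stop("curve must be calibrated first", call. = FALSE)
  ext <- curve$data[curve$data$segment == "extend", ]
  z <- ext$height_m
  if (z_c < min(z) || z_c > max(z)) {
    stop(sprintf("z_c = %.4g m lies outside the extend range [%.4g, %.4g]",
                 z_c, min(z), max(z)), call. = FALSE)
  }
  f_c <- stats::approx(z, ext$force_n, xout = z_c, ties = "ordered")$y
  d_c <- f_c / curve$spring_constant
  delta <- (z - z_c) - (ext$deflection_m - d_c)
  in_fit <- z > z_c & delta >= 0
  dat <- tibble::tibble(delta_m = delta, force_n = ext$force_n - f_c,
                        time_s = ext$time_s, in_fit = in_fit)
  t_contact <- if (any(in_fit)) {
    range(ext$time_s[in_fit])
  } else c(NA_real_, NA_real_)
  structure(
    list(data = dat, z_c = z_c, contact_force = f_c,
         t_delta = t_contact[2] - t_contact[1],
         bead_radius = curve$bead_radius,
         spring_constant = curve$spring_constant,
         setpoint_force = curve$setpoint_force,
         setpoint_speed = curve$setpoint_speed),
    class = "indentation_curve")
}

#' Fit the apparent reduced elastic modulus to a force-indentation curve
#'
#' Least-squares estimate of K for the chosen contact model over all
#' in-fit samples (extend segment past contact). Both models are linear in
#' K, so the fit is the exact one-parameter least-squares solution
#' `K = sum(F g) / sum(g^2)` with `g` the model's depth shape. A
#' non-positive estimate or an under-populated fit yields a fit-failure
#' result (`ok = FALSE`), not an error: in batch runs failed fits are data.
#'
#' `hertz_regime` records whether the maximum indentation satisfies
#' `delta_max / R < 1/3`, the regime in which the paraboloid (Hertz)
#' approximation of the sphere is considered adequate; requesting the Hertz
#' model outside it triggers a warning, never a silent model switch.
#'
#' @param ind An `indentation_curve` from [compute_indentation()].
#' @param model `"hertz"` or `"sneddon"`.
#' @param warn_regime Warn when the Hertz model is used at
#'   `delta_max / R >= 1/3` (default `TRUE`).
#' @return A `curve_fit` list: `K` (Pa), `model`, `z_c` (m), `delta_max`
#'   (m), `delta_max_over_R`, `hertz_regime`, `residual_rms` (N),
#'   `n_points_fit`, `t_delta` (s), `ok`, `failure` (reason or `NA`).
#' @export
fit_modulus <- function(ind, model = c("hertz", "sneddon"),
                        warn_regime = TRUE) {
  stopifnot(inherits(ind, "indentation_curve"))
  model <- match.arg(model)
  R <- ind$bead_radius
  dat <- ind$data[ind$data$in_fit, ]
  fail <- function(reason) {
    structure(list(K = NA_real_, model = model, z_c = ind$z_c,
                   delta_max = NA_real_, delta_max_over_R = NA_real_,
                   hertz_regime = NA, residual_rms = NA_real_,
                   n_points_fit = nrow(dat), t_delta = ind$t_delta,
                   ok = FALSE, failure = reason),
              class = "curve_fit")
  }
  if (nrow(dat) < 20) return(fail("insufficient_points"))
  delta_max <- max(dat$delta_m)
  if (delta_max >= R) {
    stop(sprintf(
      "delta_max = %.3g m is not below the probe radius %.3g m; outside the contact models' domain",
      delta_max, R), call. = FALSE)
  }
  g <- contact_shape_fun(R, model, depth_max = delta_max)(dat$delta_m)
  denom <- sum(g * g)
  if (denom <= 0) return(fail("fit_failure"))
  K <- sum(dat$force_n * g) / denom
  if (!is.finite(K) || K <= 0) return(fail("fit_failure"))
  ratio <- delta_max / R
  if (warn_regime && model == "hertz" && ratio >= 1 / 3) {
    warning(sprintf(
      "Hertz model requested at delta_max/R = %.2f (>= 1/3); consider the Sneddon model",
      ratio), call. = FALSE)
  }
  structure(
    list(K = K, model = model, z_c = ind$z_c, delta_max = delta_max,
         delta_max_over_R = ratio, hertz_regime = ratio < 1 / 3,
         residual_rms = sqrt(mean((dat$force_n - K * g)^2)),
         n_points_fit = nrow(dat), t_delta = ind$t_delta,
         ok = TRUE, failure = NA_character_),
    class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  if (x$ok) {
    cat(sprintf(
      "<curve_fit> K = %.4g Pa (%s), z_c = %.4g um, delta_max/R = %.3f%s\n",
      x$K, x$model, x$z_c * 1e6, x$delta_max_over_R,
      if (isTRUE(x$hertz_regime)) " [hertz regime]" else ""))
  } else {
    cat(sprintf("<curve_fit> failed: %s\n", x$failure))
  }
  invisible(x)
}

#' Fit the model-independent stiffness k
#'
#' Least-squares slope of force versus indentation over the samples whose
#' force lies within `window` times the maximum exerted force (default the
#' top 90-100% band). The slope k (N/m) is a model-free companion to K.
#'
#' @param ind An `indentation_curve`.
#' @param window Force-fraction window `c(lower, upper)`, default
#'   `c(0.9, 1)`.
#' @return A tibble row: `k_n_per_m`, `window_lower`, `window_upper`,
#'   `n_points`.
#' @export
fit_stiffness <- function(ind, window = c(0.9, 1)) {
  stopifnot(inherits(ind, "indentation_curve"))
  stopifnot(length(window) == 2, window[1] < window[2])
  dat <- ind$data[ind$data$in_fit, ]
  f_max <- max(dat$force_n)
  sel <- dat$force_n >= window[1] * f_max & dat$force_n <= window[2] * f_max
  if (sum(sel) < 5) {
    stop(sprintf("stiffness window holds %d samples (< 5)", sum(sel)),
         call. = FALSE)
  }
  fit <- stats::lm.fit(cbind(1, dat$delta_m[sel]), dat$force_n[sel])
  tibble::tibble(k_n_per_m = unname(fit$coefficients[2]),
                 window_lower = window[1], window_upper = window[2],
                 n_points = sum(sel))
}

#' Quality-control verdict for one curve
#'
#' A measurement is kept only when the achieved maximum force and the
#' achieved indentation speed are both within `tolerance` (default 10%) of
#' their setpoints and the modulus fit succeeded. The achieved force is the
#' maximum force on the extend segment; the achieved speed is the median
#' finite-difference piezo velocity over the in-contact part of the extend
#' segment, which is robust to turnaround transients.
#'
#' @param curve The calibrated (baseline-corrected) [force_curve()].
#' @param fit The `curve_fit` for the curve (or `NULL` for a failed fit).
#' @param tolerance Relative deviation tolerance (default 0.10).
#' @return A `qc_verdict` list: `keep`, `reasons` (character vector among
#'   `force_deviation`, `speed_deviation`, `fit_failure`,
#'   `insufficient_points`), `achieved_force` (N), `achieved_speed` (m/s).
#' @export
qc_setpoints <- function(curve, fit, tolerance = 0.10) {
  stopifnot(inherits(curve, "force_curve"))
  ext <- curve$data[curve$data$segment == "extend", ]
  achieved_force <- max(ext$force_n)
  in_contact <- if (!is.null(fit) && is.finite(fit$z_c)) {
    ext$height_m > fit$z_c
  } else rep(TRUE, nrow(ext))
  dz <- diff(ext$height_m[in_contact])
  dt <- diff(ext$time_s[in_contact])
  achieved_speed <- stats::median(dz[dt > 0] / dt[dt > 0])
  reasons <- character()
  if (is.null(fit) || !isTRUE(fit$ok)) {
    reasons <- c(reasons,
                 if (!is.null(fit) && identical(fit$failure, "insufficient_points"))
                   "insufficient_points" else "fit_failure")
  }
  rel <- function(achieved, setpoint) abs(achieved - setpoint) / setpoint
  if (is.finite(curve$setpoint_force) &&
      rel(achieved_force, curve$setpoint_force) > tolerance) {
    reasons <- c(reasons, "force_deviation")
  }
  if (is.finite(curve$setpoint_speed) &&
      rel(achieved_speed, curve$setpoint_speed) > tolerance) {
    reasons <- c(reasons, "speed_deviation")
  }
  structure(list(keep = length(reasons) == 0, reasons = reasons,
                 achieved_force = achieved_force,
                 achieved_speed = achieved_speed),
            class = "qc_verdict")
}

#' Process one force curve end to end
#'
#' The per-curve pipeline: calibrate, fit and subtract the baseline (first
#' pass over the early half of the full extend span, then once more over
#' the first half of the actual pre-contact span once a provisional contact
#' point is known), locate the contact point, fit K and k, and apply the
#' setpoint QC. Any failure downgrades to a QC-excluded row; batch runs
#' always complete.
#'
#' @param curve A [force_curve()] (raw or calibrated).
#' @param model `"hertz"` or `"sneddon"`.
#' @param qc_tolerance Relative setpoint tolerance (default 0.10).
#' @param baseline_fraction First-pass baseline fraction of the extend span.
#' @param stiffness_window Force-fraction window for [fit_stiffness()].
#' @return A one-row tibble: position, `K_pa`, `k_n_per_m`, `z_c_m`,
#'   `delta_max_m`, `delta_max_over_r`, `hertz_regime`, `model`,
#'   `residual_rms_n`, `n_fit`, `t_delta_s`, achieved force/speed, `keep`,
#'   `reasons` (comma-joined), and acquisition metadata.
#' @export
process_curve <- function(curve, model = c("hertz", "sneddon"),
                          qc_tolerance = 0.10, baseline_fraction = 0.3,
                          stiffness_window = c(0.9, 1)) {
  model <- match.arg(model)
  curve <- calibrate(curve)
  fit <- NULL
  k_row <- tibble::tibble(k_n_per_m = NA_real_)
  corrected <- curve
  step <- tryCatch({
    bl1 <- fit_baseline(curve, precontact_fraction = baseline_fraction)
    corr1 <- apply_baseline(curve, bl1)
    cp1 <- find_contact_point(corr1, model = model)
    # second pass: baseline over the first half of the true pre-contact span
    bl2 <- tryCatch(
      fit_baseline(curve, precontact_fraction = 0.5, z_max = cp1$z_c),
      error = function(e) bl1)
    corrected <- apply_baseline(curve, bl2)
    cp2 <- find_contact_point(corrected, model = model)
    fit <- cp2$fit
    ind <- compute_indentation(corrected, cp2$z_c)
    k_row <- tryCatch(fit_stiffness(ind, window = stiffness_window),
                       error = function(e) tibble::tibble(k_n_per_m = NA_real_))
    TRUE
  }, error = function(e) conditionMessage(e))
  qc <- qc_setpoints(corrected, fit, tolerance = qc_tolerance)
  tibble::tibble(
    x_m = curve$position[1], y_m = curve$position[2],
    K_pa = if (!is.null(fit) && fit$ok) fit$K else NA_real_,
    k_n_per_m = k_row$k_n_per_m[1],
    z_c_m = if (!is.null(fit)) fit$z_c else NA_real_,
    delta_max_m = if (!is.null(fit)) fit$delta_max else NA_real_,
    delta_max_over_r = if (!is.null(fit)) fit$delta_max_over_R else NA_real_,
    hertz_regime = if (!is.null(fit)) fit$hertz_regime else NA,
    model = model,
    residual_rms_n = if (!is.null(fit)) fit$residual_rms else NA_real_,
    n_fit = if (!is.null(fit)) fit$n_points_fit else 0L,
    t_delta_s = if (!is.null(fit)) fit$t_delta else NA_real_,
    achieved_force_n = qc$achieved_force,
    achieved_speed_m_s = qc$achieved_speed,
    setpoint_force_n = curve$setpoint_force,
    setpoint_speed_m_s = curve$setpoint_speed,
    keep = qc$keep,
    reasons = paste(qc$reasons, collapse = ","),
    postmortem_h = curve$postmortem_h,
    temperature_c = curve$temperature_c,
    note = if (isTRUE(step)) NA_character_ else step)
}

#' Batch-process force curves
#'
#' Maps [process_curve()] over a list of curves or a vector of curve-file
#' paths (or one directory of `.txt` curve files) and binds the per-curve
#' rows. Curve files are parsed with [read_force_curve()].
#'
#' @param curves A list of [force_curve()] objects, a character vector of
#'   file paths, or a single directory path.
#' @param ... Passed to [process_curve()].
#' @return A tibble with one row per curve, plus a `curve_file` column when
#'   reading from files.
#' @export
fit_curves <- function(curves, ...) {
  if (is.character(curves)) {
    paths <- if (length(curves) == 1 && dir.exists(curves)) {
      list.files(curves, pattern = "\\.txt$", full.names = TRUE)
    } else curves
    rows <- purrr::map(paths, function(p) {
      out <- process_curve(read_force_curve(p), ...)
      out$curve_file <- basename(p)
      out
    })
    return(dplyr::bind_rows(rows))
  }
  dplyr::bind_rows(purrr::map(curves, process_curve, ...))
}
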