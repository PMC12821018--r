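#' Measurement noise model for simulated curves
#'
#' @param deflection_sd Deflection noise SD (m). `NULL` (default) means
#'   "1% of the setpoint force", expressed in deflection through the
#'   spring constant, resolved at simulation time; `0` disables noise.
#' @param baseline_offset Constant force offset added to the whole curve
#'   (N).
#' @param baseline_tilt Linear force drift with piezo height (N/m).
#' @return A `noise_model` list.
#' @export
noise_model <- function(deflection_sd = NULL, baseline_offset = 0,
                        baseline_tilt = 0) {
  if (!is.null(deflection_sd) && deflection_sd < 0) {
    stop("`deflection_sd` must be >= 0", call. = FALSE)
  }
  structure(list(deflection_sd = deflection_sd,
                 baseline_offset = baseline_offset,
                 baseline_tilt = baseline_tilt),
            class = "noise_model")
}

#' Simulate one closed-loop force-distance curve
#'
#' Synthesises the extend (and mirrored retract) segment of a
#' constant-speed, closed-loop indentation: the piezo advances at
#' `setpoint_speed`; past the contact point the sample indents and the
#' cantilever deflects so that at piezo height `z`,
#' `z - z_c = delta + F(delta)/k_c` with `F` the chosen forward contact
#' model at the true modulus; the ramp stops when the force reaches
#' `setpoint_force` (or the piezo range `z_range` is exhausted, which
#' yields a flagged under-force curve for QC testing). The elastic
#' response is quasi-static: rate dependence enters only through the
#' condition dependence of `K_true`, never within one curve.
#'
#' Sampling runs at `sample_rate`, raised if needed so the extend segment
#' holds at least `min_extend_points` samples. Gaussian deflection noise
#' and a linear baseline (offset + tilt) are then applied. The generating
#' ground truth (`z_c`, `K_true`, `delta_max`, `t_delta`, seed) is recorded
#' in the curve's `truth` field.
#'
#' @param K_true True reduced modulus (Pa).
#' @param setpoint_force Commanded force (N); study protocols use 30-1500 nN.
#' @param setpoint_speed Piezo speed (m/s); study protocols 20-1200 um/s.
#' @param spring_constant Cantilever k_c (N/m).
#' @param bead_radius Probe radius (m); default 44.65 um.
#' @param sample_rate Base acquisition rate (Hz); default 1000.
#' @param min_extend_points Minimum extend samples (default 2500).
#' @param model Forward model generating the contact response.
#' @param noise A [noise_model()].
#' @param precontact Pre-contact approach distance (m); default 10 um.
#' @param z_range Available piezo travel (m); `Inf` for unlimited.
#' @param position,postmortem_h,temperature_c Metadata carried to the curve.
#' @param seed Integer seed; identical arguments + seed give identical
#'   curves.
#' @return A [force_curve()] (uncalibrated deflection series) with `truth`.
#' @export
simulate_curve <- function(K_true, setpoint_force = 30e-9,
                           setpoint_speed = 20e-6, spring_constant = 0.088,
                           bead_radius = 44.65e-6, sample_rate = 1000,
                           min_extend_points = 2500L,
                           model = c("hertz", "sneddon"),
                           noise = noise_model(),
                           precontact = 10e-6, z_range = Inf,
                           position = c(0, 0), postmortem_h = NA_real_,
                           temperature_c = NA_real_, seed = NULL) {
  model <- match.arg(model)
  check_positive(K_true, "K_true")
  check_positive(setpoint_force, "setpoint_force")
  check_positive(setpoint_speed, "setpoint_speed")
  check_positive(spring_constant, "spring_constant")
  stopifnot(inherits(noise, "noise_model"))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  delta_sp <- contact_depth(K_true, bead_radius, setpoint_force, model = model)
  z_full <- precontact + delta_sp + setpoint_force / spring_constant
  z_max <- min(z_full, z_range)
  reached <- z_max >= z_full - 1e-15
  t_total <- z_max / setpoint_speed
  rate <- max(sample_rate, ceiling(min_extend_points / t_total))
  n_ext <- max(min_extend_points, ceiling(t_total * rate))
  tt <- seq(0, t_total, length.out = n_ext)
  rate <- (n_ext - 1) / t_total
  z <- setpoint_speed * tt
  z_c <- precontact
  # invert z - z_c = delta + F(delta)/k_c on a dense depth grid
  dgrid <- delta_sp * seq(0, 1, length.out = 2048L)^2
  fgrid <- contact_force(K_true, bead_radius, dgrid, model = model)
  zz <- z_c + dgrid + fgrid / spring_constant
  delta <- rep(0, n_ext)
  past <- z > z_c
  delta[past] <- stats::approx(zz, dgrid, xout = pmin(z[past], max(zz)),
                               ties = "ordered")$y
  f_true <- contact_force(K_true, bead_radius, delta, model = model)
  d <- f_true / spring_constant
  sd_d <- noise$deflection_sd
  if (is.null(sd_d)) sd_d <- 0.01 * setpoint_force / spring_constant
  d <- d + (noise$baseline_offset + noise$baseline_tilt * z) / spring_constant
  if (sd_d > 0) d <- d + stats::rnorm(n_ext, sd = sd_d)
  # retract: elastic mirror at the same speed (no adhesion simulated)
  dat <- tibble::tibble(
    time_s = c(tt, t_total + tt[-1]),
    height_m = c(z, rev(z)[-1]),
    deflection_m = c(d, rev(d)[-1]),
    segment = rep(c("extend", "retract"), c(n_ext, n_ext - 1L)))
  delta_max <- max(delta)
  truth <- list(
    z_c = z_c, K_true = K_true, model = model, delta_max = delta_max,
    t_delta = (delta_max + contact_force(K_true, bead_radius, delta_max,
                                         model = model) / spring_constant) /
      setpoint_speed,
    setpoint_reached = reached, seed = seed)
  force_curve(dat, spring_constant = spring_constant,
              bead_radius = bead_radius, setpoint_force = setpoint_force,
              setpoint_speed = setpoint_speed, sample_rate = rate,
              position = position, postmortem_h = postmortem_h,
              temperature_c = temperature_c, calibrated = FALSE,
              truth = truth)
}

#' Protocol description for a simulated experiment
#'
#' @param grid_resolution Map pitch (m); study grids used 50-260 um.
#' @param setpoint_forces,setpoint_speeds Condition axes (N, m/s); the
#'   full study factorial is 30/90/150/300/600/1200/1500 nN by
#'   20/100/400/800/1200 um/s.
#' @param timepoints_h Postmortem times (h) at which the map is remeasured.
#' @param temperatures_c Sample temperatures (degree C).
#' @param spring_constant,sample_rate Cantilever and acquisition settings.
#' @param model Forward model for curve synthesis.
#' @param noise A [noise_model()].
#' @param k_scatter_sd SD of multiplicative log-normal point-to-point
#'   biological scatter on the true modulus (0 = deterministic truth).
#' @return A `protocol` list.
#' @export
protocol <- function(grid_resolution = 300e-6, setpoint_forces = 30e-9,
                     setpoint_speeds = 20e-6, timepoints_h = 1.5,
                     temperatures_c = 38, spring_constant = 0.088,
                     sample_rate = 1000, model = "hertz",
                     noise = noise_model(), k_scatter_sd = 0) {
  structure(as.list(environment()), class = "protocol")
}

#' Simulate a full mapping experiment on a phantom
#'
#' Builds the measurement grid on the phantom outline, evaluates the
#' ground-truth modulus at every position for every condition in the
#' protocol factorial (forces x speeds x timepoints x temperatures),
#' synthesises one curve per position and condition with
#' [simulate_curve()], and returns the curves together with a map manifest
#' (true compartment labels) and a ground-truth table. With `dir` set, the
#' curves are written in the package's curve dialect plus `manifest.csv`
#' and `truth.csv`, ready for [cmd_fit()]/[cmd_summarize()].
#'
#' One `seed` governs the whole experiment: per-curve seeds are spawned
#' from it by one draw of `sample.int`, so any subset of curves is
#' reproducible from the manifest alone.
#'
#' @param phantom A [make_phantom()] phantom.
#' @param protocol A [protocol()].
#' @param seed Integer master seed.
#' @param dir Optional output directory (created if missing).
#' @return A list: `curves` (list of [force_curve()]), `manifest` (tibble
#'   `x_um`, `y_um`, `curve_file`, `label`, `map_id`, condition columns,
#'   `curve_seed`), `truth` (manifest plus `K_true`).
#' @export
simulate_experiment <- function(phantom, protocol, seed = 1, dir = NULL) {
  stopifnot(inherits(phantom, "tissue_phantom"),
            inherits(protocol, "protocol"))
  grid <- build_grid(phantom$outline, protocol$grid_resolution)
  if (nrow(grid) == 0) stop("grid resolution leaves no map positions",
                            call. = FALSE)
  cond <- tidyr::expand_grid(
    setpoint_force_n = protocol$setpoint_forces,
    setpoint_speed_m_s = protocol$setpoint_speeds,
    postmortem_h = protocol$timepoints_h,
    temperature_c = protocol$temperatures_c)
  cond$map_id <- sprintf("map%03d", seq_len(nrow(cond)))
  plan <- tidyr::expand_grid(cond, grid)
  n <- nrow(plan)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  plan$curve_seed <- sample.int(.Machine$integer.max - 1L, n)
  plan$label <- phantom_compartment(phantom, plan$x_m, plan$y_m)
  K_true <- true_modulus(phantom, plan$x_m, plan$y_m,
                         force = plan$setpoint_force_n,
                         speed = plan$setpoint_speed_m_s,
                         t_pm = plan$postmortem_h,
                         temperature = plan$temperature_c)
  if (protocol$k_scatter_sd > 0) {
    K_true <- K_true * exp(stats::rnorm(n, 0, protocol$k_scatter_sd))
  }
  plan$K_true <- K_true
  plan$curve_file <- sprintf("%s_%04d.txt", plan$map_id,
                             stats::ave(seq_len(n), plan$map_id, FUN = seq_along))
  curves <- purrr::map(seq_len(n), function(i) {
    simulate_curve(
      K_true = plan$K_true[i],
      setpoint_force = plan$setpoint_force_n[i],
      setpoint_speed = plan$setpoint_speed_m_s[i],
      spring_constant = protocol$spring_constant,
      bead_radius = 44.65e-6,
      sample_rate = protocol$sample_rate,
      model = protocol$model, noise = protocol$noise,
      position = c(plan$x_m[i], plan$y_m[i]),
      postmortem_h = plan$postmortem_h[i],
      temperature_c = plan$temperature_c[i],
      seed = plan$curve_seed[i])
  })
  manifest <- tibble::tibble(
    x_um = plan$x_m * 1e6, y_um = plan$y_m * 1e6,
    curve_file = plan$curve_file, label = plan$label,
    map_id = plan$map_id,
    setpoint_force_nN = plan$setpoint_force_n * 1e9,
    setpoint_speed_um_per_s = plan$setpoint_speed_m_s * 1e6,
    postmortem_h = plan$postmortem_h,
    temperature_C = plan$temperature_c,
    curve_seed = plan$curve_seed)
  truth <- dplyr::mutate(manifest, K_true = plan$K_true)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    purrr::walk2(curves, plan$curve_file,
                 ~ write_force_curve(.x, file.path(dir, .y)))
    readr::write_csv(manifest, file.path(dir, "manifest.csv"))
    readr::write_csv(truth, file.path(dir, "truth.csv"))
  }
  list(curves = curves, manifest = manifest, truth = truth)
}

#' Simulate a multi-animal temperature study
#'
#' The end-to-end temperature experiment: `n_animals` phantom replicates
#' (each with log-normal animal-to-animal variation of the base moduli),
#' each mapped once at every temperature, every curve fitted through the
#' full pipeline, per-map compartment summaries assembled, and the
#' linear-vs-horizontal regression report computed for gray, white and the
#' gray-to-white ratio.
#'
#' Defaults mirror the study's temperature protocol: five levels spanning
#' 20-38 degrees C at 30 nN and 20 um/s, one map per animal and
#' temperature. `animal_sd` (log scale) sets how much per-animal median
#' stiffness scatters around the preset base moduli; `k_scatter_sd` adds
#' point-to-point biological heterogeneity within a map.
#'
#' @param preset Phantom preset.
#' @param temperatures_c Temperature levels (degree C).
#' @param n_animals Number of phantom replicates.
#' @param grid_resolution Map pitch (m).
#' @param animal_sd SD of the log-normal per-animal base-modulus factor.
#' @param k_scatter_sd Point-level log-normal scatter SD.
#' @param seed Master seed; per-animal seeds are spawned from it.
#' @param t_ref,alpha Passed to [regression_report()].
#' @return A list: `summaries` (per-map rows with `animal`), `report`
#'   (the [regression_report()] tibble).
#' @export
simulate_temperature_study <- function(preset = "transverse",
                                       temperatures_c = c(20, 24.5, 29, 33.5, 38),
                                       n_animals = 6,
                                       grid_resolution = 600e-6,
                                       animal_sd = 0.2, k_scatter_sd = 0.15,
                                       seed = 1, t_ref = 38, alpha = 0.05) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  animal_seeds <- sample.int(.Machine$integer.max - 1L, n_animals)
  animal_fac <- exp(stats::rnorm(2 * n_animals, 0, animal_sd))
  summaries <- purrr::map_dfr(seq_len(n_animals), function(a) {
    phantom <- make_phantom(preset,
                            K_g0 = 230 * animal_fac[2 * a - 1],
                            K_w0 = 47 * animal_fac[2 * a])
    prot <- protocol(grid_resolution = grid_resolution,
                     temperatures_c = temperatures_c,
                     k_scatter_sd = k_scatter_sd)
    ex <- simulate_experiment(phantom, prot, seed = animal_seeds[a])
    res <- fit_curves(ex$curves)
    res$curve_file <- ex$manifest$curve_file
    res |>
      dplyr::left_join(ex$manifest[, c("curve_file", "map_id")],
                       by = "curve_file") |>
      dplyr::group_split(.data$map_id) |>
      purrr::map_dfr(function(r) {
        man <- ex$manifest[ex$manifest$map_id == r$map_id[1], ]
        out <- summarize_map(as_elasticity_map(r, man))
        out$map_id <- r$map_id[1]
        out
      }) |>
      dplyr::mutate(animal = a)
  })
  list(summaries = summaries,
       report = regression_report(summaries, t_ref = t_ref, alpha = alpha))
}
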