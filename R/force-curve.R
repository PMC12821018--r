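#' Construct a force-distance curve object
#'
#' A `force_curve` bundles one indentation record (the extend and, when
#' recorded, retract segment of a single approach at one map position)
#' with its acquisition metadata and calibration. Samples live in `data`,
#' a tibble with columns `time_s`, `height_m` (piezo height), `deflection_m`
#' and `segment` (`"extend"`/`"retract"`); a `force_n` column is added by
#' [calibrate()]. All series are SI.
#'
#' @param data Tibble/data frame with at least `time_s`, `height_m`,
#'   `deflection_m`, `segment`. A pre-calibrated curve may carry `force_n`
#'   instead of `deflection_m` (set `calibrated = TRUE`).
#' @param spring_constant Cantilever spring constant k_c (N/m).
#' @param bead_radius Probe sphere radius (m).
#' @param setpoint_force Commanded maximum force (N).
#' @param setpoint_speed Commanded indentation speed (m/s).
#' @param sample_rate Acquisition rate (Hz).
#' @param sensitivity Optical lever sensitivity (m/V); metadata only.
#' @param position Numeric `c(x, y)` map position (m).
#' @param postmortem_h Time postmortem at acquisition (h), or `NA`.
#' @param temperature_c Sample temperature (degree C), or `NA`.
#' @param calibrated Whether `data` already carries a force series.
#' @param truth Optional list of generating ground truth (synthetic curves).
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(data, spring_constant, bead_radius,
                        setpoint_force = NA_real_, setpoint_speed = NA_real_,
                        sample_rate = NA_real_, sensitivity = NA_real_,
                        position = c(NA_real_, NA_real_),
                        postmortem_h = NA_real_, temperature_c = NA_real_,
                        calibrated = FALSE, truth = NULL) {
  data <- tibble::as_tibble(data)
  need <- c("time_s", "height_m", "segment",
            if (calibrated) "force_n" else "deflection_m")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0) {
    stop("curve data is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  check_positive(spring_constant, "spring_constant")
  check_positive(bead_radius, "bead_radius")
  if (sum(data$segment == "extend") < 2) {
    stop("extend segment must have at least 2 samples", call. = FALSE)
  }
  if (calibrated && !"deflection_m" %in% names(data)) {
    data$deflection_m <- data$force_n / spring_constant
  }
  structure(
    list(data = data, spring_constant = spring_constant,
         bead_radius = bead_radius, sensitivity = sensitivity,
         setpoint_force = setpoint_force, setpoint_speed = setpoint_speed,
         sample_rate = sample_rate, position = as.numeric(position),
         postmortem_h = postmortem_h, temperature_c = temperature_c,
         calibrated = isTRUE(calibrated), truth = truth),
    class = "force_curve")
}

#' @export
print.force_curve <- function(x, ...) {
  n_ext <- sum(x$data$segment == "extend")
  cat(sprintf(
    "<force_curve> %d samples (%d extend)%s\n", nrow(x$data), n_ext,
    if (x$calibrated) ", calibrated" else ""))
  cat(sprintf("  k_c = %.4g N/m, R = %.4g um, setpoint %.4g nN @ %.4g um/s\n",
              x$spring_constant, x$bead_radius * 1e6,
              x$setpoint_force * 1e9, x$setpoint_speed * 1e6))
  if (!is.null(x$truth)) {
    cat(sprintf("  synthetic: K_true = %.4g Pa, z_c = %.4g um\n",
                x$truth$K_true, x$truth$z_c * 1e6))
  }
  invisible(x)
}

#' Cantilever calibration record
#'
#' @param spring_constant Spring constant k_c (N/m); the study cantilevers
#'   span 0.083-2.757 N/m.
#' @param sensitivity Deflection sensitivity (m/V).
#' @param id Identifier string.
#' @return A `cantilever` list.
#' @export
cantilever <- function(spring_constant, sensitivity = NA_real_, id = "") {
  check_positive(spring_constant, "spring_constant")
  structure(list(spring_constant = spring_constant,
                 sensitivity = sensitivity, id = id),
            class = "cantilever")
}

#' Attach a force series to a curve
#'
#' Converts the deflection series to force with the cantilever law
#' `F = k_c * d`. Idempotent: calibrating an already calibrated curve with
#' the same spring constant is a no-op; a conflicting spring constant is an
#' error because it would silently rescale forces.
#'
#' @param curve A [force_curve()].
#' @param cantilever Optional [cantilever()]; defaults to the curve's own
#'   spring constant.
#' @return The curve with a `force_n` column and `calibrated = TRUE`.
#' @export
calibrate <- function(curve, cantilever = NULL) {
  stopifnot(inherits(curve, "force_curve"))
  k_c <- if (is.null(cantilever)) curve$spring_constant else {
    stopifnot(inherits(cantilever, "cantilever"))
    cantilever$spring_constant
  }
  if (curve$calibrated) {
    if (!isTRUE(all.equal(k_c, curve$spring_constant, tolerance = 1e-9))) {
      stop("curve is already calibrated with a different spring constant (",
           curve$spring_constant, " N/m)", call. = FALSE)
    }
    return(curve)
  }
  curve$spring_constant <- k_c
  curve$data$force_n <- k_c * curve$data$deflection_m
  curve$calibrated <- TRUE
  curve
}

# --- curve-file dialect ----------------------------------------------------
# UTF-8 text, "# key: value" header lines, then tab-separated columns
# time_s, height_m, deflection_m (or force_n when "# calibrated: true").
# Header units follow instrument convention (nN, um) and are converted to
# SI on read; one curve per file, a directory of files is a map.

curve_header_keys <- c(
  "spring_constant_N_per_m", "sensitivity_m_per_V", "bead_radius_um",
  "setpoint_force_nN", "setpoint_speed_um_per_s", "sample_rate_Hz",
  "position_x_um", "position_y_um", "postmortem_h", "temperature_C",
  "extend_points", "calibrated")

#' Read a force-distance curve file
#'
#' Parses the package's plain-text curve dialect (see
#' `vignette("afm-elasticity-mapping")`): `# key: value` header lines with
#' instrument units (nN, um), then tab-separated samples. All values are
#' converted to SI on load.
#'
#' @param path Path to a curve file.
#' @return A [force_curve()].
#' @export
read_force_curve <- function(path) {
  if (!file.exists(path)) stop("no such curve file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_hdr <- startsWith(lines, "#")
  hdr_lines <- lines[is_hdr]
  kv <- regmatches(hdr_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", hdr_lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad) > 0) {
    stop(sprintf("%s: malformed header line %d: %s", path, bad[1],
                 hdr_lines[bad[1]]), call. = FALSE)
  }
  hdr <- stats::setNames(
    trimws(vapply(kv, `[`, character(1), 3)),
    trimws(vapply(kv, `[`, character(1), 2)))
  unknown <- setdiff(names(hdr), c(curve_header_keys, "truth_json"))
  if (length(unknown) > 0) {
    stop(sprintf("%s: unknown header key(s): %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  need <- function(key) {
    if (!key %in% names(hdr) || hdr[[key]] == "") {
      stop(sprintf("%s: required header field `%s` is missing", path, key),
           call. = FALSE)
    }
    as.numeric(hdr[[key]])
  }
  opt <- function(key) {
    if (key %in% names(hdr) && hdr[[key]] != "") as.numeric(hdr[[key]]) else NA_real_
  }
  calibrated <- "calibrated" %in% names(hdr) &&
    identical(tolower(hdr[["calibrated"]]), "true")
  body <- lines[!is_hdr]
  body <- body[nzchar(body)]
  cols <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  value_col <- if (calibrated) "force_n" else "deflection_m"
  expect <- c("time_s", "height_m", value_col)
  if (!identical(cols, expect)) {
    stop(sprintf("%s: expected columns %s, found %s", path,
                 paste(expect, collapse = "/"), paste(cols, collapse = "/")),
         call. = FALSE)
  }
  mat <- utils::read.table(text = body[-1], sep = "\t", header = FALSE,
                           col.names = cols, colClasses = "numeric")
  n_ext <- as.integer(need("extend_points"))
  if (n_ext < 2 || n_ext > nrow(mat)) {
    stop(sprintf("%s: extend_points (%d) inconsistent with %d samples", path,
                 n_ext, nrow(mat)), call. = FALSE)
  }
  dat <- tibble::as_tibble(mat)
  dat$segment <- rep(c("extend", "retract"), c(n_ext, nrow(mat) - n_ext))
  truth <- if ("truth_json" %in% names(hdr)) {
    jsonlite::fromJSON(hdr[["truth_json"]])
  }
  force_curve(
    dat,
    spring_constant = need("spring_constant_N_per_m"),
    bead_radius = need("bead_radius_um") * 1e-6,
    setpoint_force = opt("setpoint_force_nN") * 1e-9,
    setpoint_speed = opt("setpoint_speed_um_per_s") * 1e-6,
    sample_rate = opt("sample_rate_Hz"),
    sensitivity = opt("sensitivity_m_per_V"),
    position = c(opt("position_x_um"), opt("position_y_um")) * 1e-6,
    postmortem_h = opt("postmortem_h"),
    temperature_c = opt("temperature_C"),
    calibrated = calibrated, truth = truth)
}

#' Write a force-distance curve file
#'
#' Inverse of [read_force_curve()]; numeric series are written with 17
#' significant digits so a write/read round trip reproduces the arrays to
#' machine precision.
#'
#' @param curve A [force_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  num <- function(x) {
    ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))
  }
  hdr <- c(
    spring_constant_N_per_m = num(curve$spring_constant),
    sensitivity_m_per_V = num(curve$sensitivity),
    bead_radius_um = num(curve$bead_radius * 1e6),
    setpoint_force_nN = num(curve$setpoint_force * 1e9),
    setpoint_speed_um_per_s = num(curve$setpoint_speed * 1e6),
    sample_rate_Hz = num(curve$sample_rate),
    position_x_um = num(curve$position[1] * 1e6),
    position_y_um = num(curve$position[2] * 1e6),
    postmortem_h = num(curve$postmortem_h),
    temperature_C = num(curve$temperature_c),
    extend_points = sum(curve$data$segment == "extend"),
    calibrated = tolower(as.character(curve$calibrated)))
  if (!is.null(curve$truth)) {
    hdr <- c(hdr, truth_json = as.character(
      jsonlite::toJSON(curve$truth, auto_unbox = TRUE, digits = NA)))
  }
  value_col <- if (curve$calibrated) "force_n" else "deflection_m"
  dat <- curve$data[, c("time_s", "height_m", value_col)]
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# ", names(hdr), ": ", hdr), con)
  writeLines(paste(names(dat), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(dat, num), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
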