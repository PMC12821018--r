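test_that("calibration applies the cantilever law and is idempotent", {
  n <- 100
  dat <- tibble::tibble(time_s = seq_len(n) / 1000,
                        height_m = seq_len(n) * 1e-8,
                        deflection_m = rep(100e-9, n),
                        segment = "extend")
  cv <- force_curve(dat, spring_constant = 0.3, bead_radius = R_STUDY)
  cal <- calibrate(cv)
  expect_equal(cal$data$force_n, rep(30e-9, n))  # 100 nm * 0.3 N/m = 30 nN
  expect_identical(calibrate(cal)$data$force_n, cal$data$force_n)
  expect_error(calibrate(cal, cantilever(0.5)), "different spring constant")
  dat$deflection_m <- 0
  cv0 <- calibrate(force_curve(dat, 0.3, R_STUDY))
  expect_equal(cv0$data$force_n, rep(0, n))
})

test_that("baseline fit recovers a known offset and tilt", {
  cv <- simulate_curve(250, seed = 5,
                       noise = noise_model(deflection_sd = 0.1e-9,
                                           baseline_offset = 0.5e-9,
                                           baseline_tilt = 1e-5))
  bl <- fit_baseline(calibrate(cv), precontact_fraction = 0.3)
  # recovered within a loose multiple of the noise scale
  expect_equal(bl$offset, 0.5e-9, tolerance = 0.05)
  expect_equal(bl$tilt, 1e-5, tolerance = 0.05)
  # flat noise-free baseline -> (0, 0)
  bl0 <- fit_baseline(calibrate(noisefree_curve()), precontact_fraction = 0.3)
  expect_equal(bl0$offset, 0, tolerance = 1e-18)
  expect_equal(bl0$tilt, 0, tolerance = 1e-12)
})

test_that("a curve with no pre-contact region yields an insufficient-data error", {
  cv <- noisefree_curve()
  ext <- cv$data[cv$data$segment == "extend", ]
  ext <- ext[ext$height_m > cv$truth$z_c + 1e-7, ]  # drop everything pre-contact
  cut <- force_curve(ext, cv$spring_constant, cv$bead_radius,
                     setpoint_force = cv$setpoint_force,
                     setpoint_speed = cv$setpoint_speed)
  expect_error(fit_baseline(calibrate(cut), precontact_fraction = 0.001),
               "baseline window")
})

test_that("contact point is recovered exactly on noise-free curves", {
  for (model in c("hertz", "sneddon")) {
    cv <- noisefree_curve(K = 300, model = model)
    cp <- find_contact_point(calibrate(cv), model = model)
    expect_lt(abs(cp$z_c - cv$truth$z_c), 0.1e-6)
    expect_equal(cp$fit$K, 300, tolerance = 1e-3)
  }
})

test_that("contact point is robust to 1% deflection noise across seeds", {
  hits <- vapply(1:60, function(s) {
    cv <- simulate_curve(250, seed = s)  # default noise: 1% of setpoint
    row <- process_curve(cv)
    abs(row$z_c_m - cv$truth$z_c) < 0.5e-6
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("a pure-baseline curve that never contacts raises contact-not-found", {
  set.seed(9)
  n <- 2500
  dat <- tibble::tibble(time_s = seq_len(n) / 1000,
                        height_m = seq_len(n) * 8e-9,
                        deflection_m = rnorm(n, sd = 1e-9),
                        segment = "extend")
  cv <- calibrate(force_curve(dat, 0.088, R_STUDY))
  expect_error(find_contact_point(cv), "contact not found")
})

test_that("indentation kinematics handle the rigid and free limits", {
  n <- 200
  z <- seq_len(n) * 1e-8
  z_c <- z[50]
  # rigid sample: deflection rises 1:1 with z past contact -> delta == 0
  d_rigid <- pmax(z - z_c, 0)
  cv <- calibrate(force_curve(
    tibble::tibble(time_s = z / 2e-5, height_m = z, deflection_m = d_rigid,
                   segment = "extend"), 0.5, R_STUDY))
  ind <- compute_indentation(cv, z_c)
  expect_equal(max(abs(ind$data$delta_m[ind$data$in_fit])), 0,
               tolerance = 1e-12)
  # free cantilever: d == 0 -> delta = z - z_c
  cv0 <- calibrate(force_curve(
    tibble::tibble(time_s = z / 2e-5, height_m = z, deflection_m = 0,
                   segment = "extend"), 0.5, R_STUDY))
  ind0 <- compute_indentation(cv0, z_c)
  expect_equal(ind0$data$delta_m, z - z_c, tolerance = 1e-15)
  expect_error(compute_indentation(cv0, max(z) + 1e-6), "outside")
})

test_that("maximum indentation matches the generator's ground truth", {
  cv <- calibrate(noisefree_curve(K = 180))
  ind <- compute_indentation(cv, cv$truth$z_c)
  expect_equal(max(ind$data$delta_m[ind$data$in_fit]), cv$truth$delta_max,
               tolerance = 1e-3)
})

test_that("modulus fit recovers K and flags the Hertz-regime threshold", {
  cv <- calibrate(noisefree_curve(K = 250))
  ind <- compute_indentation(cv, cv$truth$z_c)
  fit <- fit_modulus(ind, "hertz")
  expect_equal(fit$K, 250, tolerance = 1e-3)
  expect_true(fit$ok)
  # 14 um on the 44.65 um probe: 0.314 < 1/3 -> still hertz regime
  expect_true(14e-6 / R_STUDY < 1 / 3)
  expect_identical(fit$hertz_regime, fit$delta_max_over_R < 1 / 3)
})

test_that("fitting a deep Sneddon curve with Hertz is biased; with Sneddon exact", {
  f_deep <- sneddon_force(250, R_STUDY, 0.5 * R_STUDY)
  cv <- calibrate(noisefree_curve(K = 250, force = f_deep, speed = 400e-6,
                                  k_c = 2, model = "sneddon"))
  ind <- compute_indentation(cv, cv$truth$z_c)
  fit_s <- fit_modulus(ind, "sneddon")
  expect_equal(fit_s$K, 250, tolerance = 1e-3)
  expect_warning(fit_h <- fit_modulus(ind, "hertz"), "Sneddon")
  expect_gt(abs(fit_h$K - 250) / 250, 0.01)
})

test_that("a non-contact indentation curve yields a failure verdict, not an error", {
  n <- 200
  z <- seq_len(n) * 1e-8
  cv <- calibrate(force_curve(
    tibble::tibble(time_s = z / 2e-5, height_m = z,
                   deflection_m = -1e-9 * seq_len(n) / n,  # force decreasing
                   segment = "extend"), 0.5, R_STUDY))
  fit <- fit_modulus(compute_indentation(cv, z[20]), "hertz")
  expect_false(fit$ok)
  expect_identical(fit$failure, "fit_failure")
})

test_that("stiffness slope matches a linear curve exactly and the Hertz tangent approximately", {
  # exact linear force-indentation data: k = 0.01 N/m
  n <- 300
  delta <- seq(0, 5e-6, length.out = n)
  cvlin <- calibrate(force_curve(
    tibble::tibble(time_s = seq_len(n) / 1000,
                   height_m = delta + 0.01 * delta / 0.5,
                   deflection_m = 0.01 * delta / 0.5, segment = "extend"),
    0.5, R_STUDY))
  # on this fabricated record deflection tracks 0.01*delta/k_c so F = 0.01*delta
  ind <- compute_indentation(cvlin, 0)
  expect_equal(fit_stiffness(ind)$k_n_per_m, 0.01, tolerance = 1e-9)
  # noise-free Hertz: within 3% of the analytic tangent 2 K sqrt(R delta_max)
  cv <- calibrate(noisefree_curve(K = 250))
  indh <- compute_indentation(cv, cv$truth$z_c)
  k_hat <- fit_stiffness(indh)$k_n_per_m
  k_tan <- 2 * 250 * sqrt(R_STUDY * cv$truth$delta_max)
  expect_lt(abs(k_hat / k_tan - 1), 0.03)
  # the default window keeps enough of a 2500-point curve
  expect_gte(fit_stiffness(indh)$n_points, 5)
})

test_that("setpoint QC applies the 10% exclusion rule", {
  mk <- function(f_scale) {
    cv <- noisefree_curve(K = 250)
    cv <- calibrate(cv)
    cv$data$force_n <- cv$data$force_n * f_scale
    cv$data$deflection_m <- cv$data$force_n / cv$spring_constant
    cv
  }
  fit_ok <- structure(list(ok = TRUE, z_c = 1e-5), class = "curve_fit")
  # 32/30 nN = 6.7% deviation -> keep
  qc1 <- qc_setpoints(mk(32 / 30), fit_ok)
  expect_true(qc1$keep)
  # 26/30 nN = 13.3% -> excluded for force deviation
  qc2 <- qc_setpoints(mk(26 / 30), fit_ok)
  expect_false(qc2$keep)
  expect_true("force_deviation" %in% qc2$reasons)
  # failed fit excludes regardless of setpoints
  qc3 <- qc_setpoints(mk(1), structure(list(ok = FALSE, z_c = NA_real_,
                                            failure = "fit_failure"),
                                       class = "curve_fit"))
  expect_false(qc3$keep)
  expect_true("fit_failure" %in% qc3$reasons)
})

test_that("full pipeline is invariant to height translation and baseline within 2%", {
  cv <- simulate_curve(250, seed = 21)
  base <- process_curve(cv)
  shifted <- cv
  shifted$data$height_m <- shifted$data$height_m + 7e-6
  rs <- process_curve(shifted)
  expect_lt(abs((rs$z_c_m - base$z_c_m) - 7e-6), 1e-9)
  expect_equal(rs$K_pa, base$K_pa, tolerance = 1e-6)
  cvb <- simulate_curve(250, seed = 21,
                        noise = noise_model(baseline_offset = 0.5e-9,
                                            baseline_tilt = 1e-5))
  rb <- process_curve(cvb)
  expect_equal(rb$K_pa, base$K_pa, tolerance = 0.02)
})

test_that("curve files round trip through the dialect losslessly", {
  cv <- simulate_curve(250, seed = 13, position = c(1e-4, 2e-4),
                       postmortem_h = 2.5, temperature_c = 32)
  path <- withr::local_tempfile(fileext = ".txt")
  write_force_curve(cv, path)
  back <- read_force_curve(path)
  expect_equal(back$data$height_m, cv$data$height_m, tolerance = 1e-12)
  expect_equal(back$data$deflection_m, cv$data$deflection_m, tolerance = 1e-12)
  expect_equal(back$setpoint_force, cv$setpoint_force)
  expect_equal(back$position, cv$position)
  expect_equal(back$truth$K_true, cv$truth$K_true)
  expect_identical(sum(back$data$segment == "extend"),
                   sum(cv$data$segment == "extend"))
})

test_that("a curve file without a spring constant is rejected by field name", {
  cv <- simulate_curve(250, seed = 13)
  path <- withr::local_tempfile(fileext = ".txt")
  write_force_curve(cv, path)
  lines <- readLines(path)
  writeLines(lines[!grepl("spring_constant", lines)], path)
  expect_error(read_force_curve(path), "spring_constant_N_per_m")
  expect_error(read_force_curve("does/not/exist.txt"), "no such")
})

test_that("fitted K and fitted k are strongly correlated across a population", {
  set.seed(31)
  K_true <- exp(runif(25, log(60), log(900)))
  rows <- purrr::map_dfr(seq_along(K_true), function(i)
    process_curve(simulate_curve(K_true[i], seed = 1000 + i)))
  expect_gt(correlate_K_k(rows)$pearson_r, 0.9)
})
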