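test_that("phantom presets are deterministic and validated", {
  p1 <- make_phantom("transverse")
  p2 <- make_phantom("transverse")
  expect_identical(p1, p2)
  # gray region strictly inside the outline
  area <- function(poly) abs(sum(poly[, 1] * c(poly[-1, 2], poly[1, 2]) -
                                   poly[, 2] * c(poly[-1, 1], poly[1, 1]))) / 2
  expect_lt(sum(vapply(p1$gray, area, numeric(1))), area(p1$outline))
  expect_true(all(vapply(p1$gray, function(g)
    all(pracma::inpolygon(g[, 1], g[, 2],
                          p1$outline[, 1], p1$outline[, 2])),
    logical(1))))
  expect_error(make_phantom("transverse", K_g0 = -1), "K_g0")
  expect_error(response_model(f_end = 0), "f_end")
})

test_that("ground-truth modulus composes the response factors in closed form", {
  ph <- make_phantom("transverse")
  # gray point at reference-ish conditions: independent arithmetic
  x <- -0.45e-3; y <- 0
  r <- ph$response$gray
  f_fac <- 1 + r$A_f * (1 - exp(-30e-9 / r$F_c))
  s_fac <- 1 + r$A_s * (1 - exp(-20e-6 / r$s_c))
  t_mid <- (r$t_on + r$t_off) / 2; w <- (r$t_off - r$t_on) / 8
  pm_fac <- r$f_end + (1 - r$f_end) / (1 + exp((1.5 - t_mid) / w))
  temp_fac <- 1 + r$rho / 100 * (32.5 - 38)
  expect_equal(true_modulus(ph, x, y, 30e-9, 20e-6, 1.5, 32.5),
               230 * f_fac * s_fac * pm_fac * temp_fac, tolerance = 1e-12)
  # colder tissue is stiffer in both compartments
  expect_gt(true_modulus(ph, x, y, temperature = 20),
            true_modulus(ph, x, y, temperature = 38))
  expect_gt(true_modulus(ph, 1.5e-3, 0, temperature = 20),
            true_modulus(ph, 1.5e-3, 0, temperature = 38))
  # gray matter pre-onset plateau: factor ~ 1 at 2 h
  expect_equal(true_modulus(ph, x, y, t_pm = 2) /
                 true_modulus(ph, x, y, t_pm = 0), 1, tolerance = 1e-2)
  expect_error(true_modulus(ph, 10e-3, 0), "outside")
})

test_that("postmortem decay reaches the terminal plateau fractions", {
  ph <- make_phantom("transverse")
  late_over_early <- function(comp_xy) {
    true_modulus(ph, comp_xy[1], comp_xy[2], t_pm = 12) /
      true_modulus(ph, comp_xy[1], comp_xy[2], t_pm = 0)
  }
  expect_equal(late_over_early(c(-0.45e-3, 0)), 2 / 3, tolerance = 0.01)
  expect_equal(late_over_early(c(1.5e-3, 0)), 1 / 2, tolerance = 0.01)
})

test_that("simulated curves honour the closed-loop kinematics and determinism", {
  cv <- noisefree_curve(K = 250)
  # recorded depth equals the closed-form Hertz inverse at the setpoint
  expect_equal(cv$truth$delta_max, hertz_depth(250, R_STUDY, 30e-9),
               tolerance = 1e-6)
  # indentation duration: (depth + deflection travel) / speed
  expect_equal(cv$truth$t_delta,
               (cv$truth$delta_max + 30e-9 / 0.088) / 20e-6,
               tolerance = 1e-6)
  # achieved force reaches the setpoint
  cal <- calibrate(cv)
  expect_equal(max(cal$data$force_n), 30e-9, tolerance = 1e-3)
  expect_gte(sum(cv$data$segment == "extend"), 2500)
  # same seed -> bit-identical arrays
  a <- simulate_curve(250, seed = 77)
  b <- simulate_curve(250, seed = 77)
  expect_identical(a$data, b$data)
  c2 <- simulate_curve(250, seed = 78)
  expect_false(identical(a$data, c2$data))
})

test_that("an unreachable setpoint yields a flagged short curve, not an error", {
  cv <- simulate_curve(250, seed = 5, z_range = 12e-6,
                       noise = noise_model(deflection_sd = 0))
  expect_false(cv$truth$setpoint_reached)
  cal <- calibrate(cv)
  expect_lt(max(cal$data$force_n), 0.9 * 30e-9)
})

test_that("experiment simulation conserves counts and writes a readable directory", {
  ph <- make_phantom("transverse")
  dir <- withr::local_tempdir()
  ex <- simulate_experiment(ph, protocol(grid_resolution = 800e-6),
                            seed = 3, dir = dir)
  n_pos <- nrow(build_grid(ph$outline, 800e-6))
  expect_identical(length(ex$curves), n_pos)
  expect_identical(nrow(ex$manifest), n_pos)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_identical(length(list.files(dir, pattern = "^map.*txt$")), n_pos)
  # factorial: 2 forces x 2 speeds on the same grid
  ex2 <- simulate_experiment(
    ph, protocol(grid_resolution = 800e-6,
                 setpoint_forces = c(30e-9, 90e-9),
                 setpoint_speeds = c(20e-6, 100e-6)), seed = 3)
  expect_identical(length(ex2$curves), 4L * n_pos)
  # determinism of the whole experiment
  ex3 <- simulate_experiment(ph, protocol(grid_resolution = 800e-6), seed = 3)
  expect_identical(ex$manifest, ex3$manifest)
  expect_identical(ex$curves[[1]]$data, ex3$curves[[1]]$data)
  # written curve round trips to the in-memory object
  back <- read_force_curve(file.path(dir, ex$manifest$curve_file[1]))
  expect_equal(back$data$deflection_m, ex$curves[[1]]$data$deflection_m,
               tolerance = 1e-12)
})

test_that("pipeline closes the loop on noise-free simulated maps", {
  ph <- make_phantom("transverse")
  ex <- simulate_experiment(ph, protocol(grid_resolution = 800e-6,
                                         noise = noise_model(deflection_sd = 0)),
                            seed = 9)
  res <- fit_curves(ex$curves)
  expect_true(all(res$keep))
  expect_lt(max(abs(res$K_pa / ex$truth$K_true - 1)), 0.01)
})

test_that("gray-to-white ratio declines along the force axis on default phantoms", {
  ph <- make_phantom("transverse")
  forces <- c(30, 150, 600, 1500) * 1e-9
  gx <- c(-0.45e-3, 0); wx <- c(1.5e-3, 0)
  ratio <- vapply(forces, function(f) {
    true_modulus(ph, gx[1], gx[2], force = f) /
      true_modulus(ph, wx[1], wx[2], force = f)
  }, numeric(1))
  expect_true(all(diff(ratio) < 0))
})
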