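test_that("grid construction matches a brute-force point-in-polygon count", {
  # 1 mm square at 200 um pitch: cell-centre lattice -> exactly 5 x 5
  square <- cbind(c(0, 1e-3, 1e-3, 0), c(0, 0, 1e-3, 1e-3))
  g <- build_grid(square, 200e-6)
  expect_identical(nrow(g), 25L)
  # ordering: row-major, x fast
  expect_equal(g$x_m[1:5], seq(1e-4, 9e-4, by = 2e-4))
  expect_equal(g$y_m[1:5], rep(1e-4, 5))
  # brute-force oracle on an irregular polygon chosen off the lattice
  tri <- cbind(c(0.013e-3, 1.017e-3, 0.441e-3), c(0.011e-3, 0.083e-3, 0.967e-3))
  gt <- build_grid(tri, 119e-6)
  xs <- seq(0.013e-3 + 119e-6 / 2, 1.017e-3, by = 119e-6)
  ys <- seq(0.011e-3 + 119e-6 / 2, 0.967e-3, by = 119e-6)
  lattice <- expand.grid(x = xs, y = ys)
  oracle <- lattice[brute_force_in_poly(lattice$x, lattice$y, tri), ]
  expect_identical(nrow(gt), nrow(oracle))
  expect_setequal(paste(round(gt$x_m * 1e9), round(gt$y_m * 1e9)),
                  paste(round(oracle$x * 1e9), round(oracle$y * 1e9)))
  expect_error(build_grid(cbind(c(0, 1, 2), c(0, 0, 0)), 0.1), "degenerate")
})

test_that("grid construction is deterministic and oversize pitch never errors", {
  square <- cbind(c(0, 1e-3, 1e-3, 0), c(0, 0, 1e-3, 1e-3))
  g <- build_grid(square, 200e-6)
  expect_identical(build_grid(square, 200e-6), g)
  # a convex outline equals its own hull, so rebuilding there is a no-op
  expect_identical(build_grid(square[grDevices::chull(square), ], 200e-6), g)
  big <- build_grid(square, 5e-3)
  expect_s3_class(big, "tbl_df")
  # pitch larger than the extent leaves the single central cell point
  expect_identical(nrow(build_grid(square, 1.2e-3)), 1L)
})

test_that("repeat aggregation averages only QC-passing results", {
  res <- tibble::tibble(K_pa = c(100, 110), keep = c(TRUE, TRUE))
  expect_equal(aggregate_repeats(res)$K_pa, 105)
  one <- tibble::tibble(K_pa = 123, keep = TRUE)
  expect_equal(aggregate_repeats(one)$K_pa, 123)
  mix <- tibble::tibble(K_pa = c(100, 500), keep = c(TRUE, FALSE))
  expect_equal(aggregate_repeats(mix)$K_pa, 100)
  none <- tibble::tibble(K_pa = c(NA_real_, 500), keep = c(TRUE, FALSE))
  out <- aggregate_repeats(none)
  expect_true(is.na(out$K_pa))
  expect_identical(out$reason, "all_excluded")
})

map_fixture <- function(gray = c(2, 3, 4), white = c(1, 1, 3),
                        excluded = numeric()) {
  k <- c(gray, white, excluded)
  n <- length(k)
  tibble::tibble(
    x_um = seq_len(n) * 10, y_um = 0, K_pa = k,
    label = rep(c("gray", "white", "excluded"),
                c(length(gray), length(white), length(excluded))),
    n_used = 1L, postmortem_h = 2, temperature_c = 25)
}

test_that("map summary computes per-compartment medians and their ratio", {
  s <- summarize_map(map_fixture())
  expect_equal(s$median_K_gray, 3)
  expect_equal(s$median_K_white, 1)
  expect_equal(s$ratio, 3)
  expect_identical(c(s$n_gray, s$n_white), c(3L, 3L))
  # all-white map: medians still reported, ratio missing
  sw <- summarize_map(map_fixture(gray = numeric()))
  expect_true(is.na(sw$ratio))
  expect_equal(sw$median_K_white, 1)
})

test_that("map summary ignores entry order, duplication and excluded labels", {
  m <- map_fixture()
  s <- summarize_map(m)
  expect_equal(summarize_map(m[sample(nrow(m)), ]), s)
  expect_equal(summarize_map(dplyr::bind_rows(m, m))[, c(1:3)], s[, 1:3])
  poisoned <- dplyr::bind_rows(m, map_fixture(gray = numeric(),
                                              white = numeric(),
                                              excluded = rep(1e6, 10)))
  expect_equal(summarize_map(poisoned)[, 1:5], s[, 1:5])
})

test_that("scaling all K scales medians but not the ratio", {
  m <- map_fixture(gray = c(10, 20, 80), white = c(5, 7, 30))
  s1 <- summarize_map(m)
  m2 <- dplyr::mutate(m, K_pa = K_pa * 3.7)
  s2 <- summarize_map(m2)
  expect_equal(s2$median_K_gray, 3.7 * s1$median_K_gray)
  expect_equal(s2$ratio, s1$ratio)
})

test_that("time binning uses one-hour bins from 1.5 h and conserves counts", {
  d <- tibble::tibble(t = c(1.6, 2.0, 2.6, 5.1, 1.2), v = c(10, 20, 7, 5, 99))
  b <- bin_timeseries(d, time = "t", value = "v")
  first <- b[b$bin_start_h == 1.5, ]
  expect_equal(first$mean, 15)
  expect_equal(first$sd, sd(c(10, 20)))
  expect_identical(first$n, 2L)
  # singleton bin: sd missing
  expect_true(is.na(b$sd[b$bin_start_h == 4.5]))
  # record before 1.5 h lands in a flagged underflow bin, not dropped
  expect_true(any(b$underflow))
  expect_identical(sum(b$n), nrow(d))
  expect_error(bin_timeseries(tibble::tibble(t = c(1, NA), v = 1:2),
                              time = "t", value = "v"), "finite time")
})

test_that("positions mismatched between results and manifest are an error", {
  res <- tibble::tibble(x_um = c(0, 10), y_um = 0, K_pa = c(100, 200),
                        keep = TRUE, postmortem_h = 2, temperature_c = 25)
  man <- tibble::tibble(x_um = c(0, 20), y_um = 0,
                        label = c("gray", "white"))
  expect_error(as_elasticity_map(res, man), "position mismatch")
  man_ok <- tibble::tibble(x_um = c(0, 10), y_um = 0,
                           label = c("gray", "white"))
  m <- as_elasticity_map(res, man_ok)
  expect_s3_class(m, "elasticity_map")
  expect_identical(nrow(m), 2L)
  expect_s3_class(autoplot(m), "ggplot")
})

test_that("half-comparison is symmetric on identical halves and detects injected softening", {
  mk_half <- function(half, soften = 1) tibble::tibble(
    half = half, timepoint_h = c(2, 6),
    median_K_gray = c(200, 150 * soften),
    median_K_white = c(100, 60 * soften))
  sym <- compare_halves(dplyr::bind_rows(mk_half("a"), mk_half("b")))
  expect_equal(sym$between$change_ratio_gray, 1)
  expect_equal(sym$between$change_ratio_white, 1)
  inj <- compare_halves(dplyr::bind_rows(mk_half("a", soften = 0.8),
                                         mk_half("b")))
  expect_lt(inj$between$change_ratio_gray, 1)
  one <- mk_half("a")[1, ]
  expect_error(compare_halves(dplyr::bind_rows(one, mk_half("b"))),
               "lacks first and last")
})
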