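# Shared fixtures, built in code at test time.

R_STUDY <- 44.65e-6  # probe radius (m)

# quiet noise-free curve at study defaults
noisefree_curve <- function(K = 250, force = 30e-9, speed = 20e-6,
                            k_c = 0.088, model = "hertz", seed = 1, ...) {
  simulate_curve(K, setpoint_force = force, setpoint_speed = speed,
                 spring_constant = k_c, model = model,
                 noise = noise_model(deflection_sd = 0), seed = seed, ...)
}

# independent brute-force OLS for the linear-vs-constant comparison:
# closed-form normal equations, no lm(), no shared code path
brute_force_lvc <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  a <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  b <- (sy - a * sx) / n
  rss_alt <- sum((y - a * x - b)^2)
  rss_null <- sum((y - sy / n)^2)
  f <- (rss_null - rss_alt) / (rss_alt / (n - 2))
  list(slope = a, intercept = b, rss_null = rss_null, rss_alt = rss_alt,
       f = f, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# brute-force point-in-polygon by ray casting (even-odd), boundary inside
brute_force_in_poly <- function(px, py, poly) {
  vapply(seq_along(px), function(i) {
    x <- px[i]; y <- py[i]
    n <- nrow(poly)
    on_edge <- FALSE
    inside <- FALSE
    for (j in seq_len(n)) {
      k <- if (j == n) 1L else j + 1L
      x1 <- poly[j, 1]; y1 <- poly[j, 2]
      x2 <- poly[k, 1]; y2 <- poly[k, 2]
      cross <- (x2 - x1) * (y - y1) - (y2 - y1) * (x - x1)
      if (abs(cross) < 1e-18 && min(x1, x2) - 1e-12 <= x &&
          x <= max(x1, x2) + 1e-12 && min(y1, y2) - 1e-12 <= y &&
          y <= max(y1, y2) + 1e-12) {
        on_edge <- TRUE
      }
      if ((y1 > y) != (y2 > y) &&
          x < x1 + (y - y1) * (x2 - x1) / (y2 - y1)) {
        inside <- !inside
      }
    }
    inside || on_edge
  }, logical(1))
}
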