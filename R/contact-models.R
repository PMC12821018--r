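#' Hertz contact force for a spherical indenter
#'
#' Force exerted by a rigid sphere of radius `radius` indenting an elastic
#' half-space of reduced apparent elastic modulus `K` to depth `depth`,
#' under the Hertz (paraboloid) approximation
#' \deqn{F = \frac{4}{3} K \sqrt{R}\, \delta^{3/2}.}
#' `K = E/(1 - \nu^2)` is reported instead of the Young's modulus so that no
#' Poisson's ratio needs to be assumed. The paraboloid approximation is
#' accurate for shallow contact (`depth/radius < 1/3`); for deeper
#' indentation use [sneddon_force()].
#'
#' All quantities are SI: metres, newtons, pascals.
#'
#' @param K Reduced apparent elastic modulus (Pa), `> 0`.
#' @param radius Sphere radius (m), `> 0`. The study probe is 44.65 um.
#' @param depth Indentation depth (m), `>= 0`. Vectorised.
#' @return Force (N), same length as `depth`.
#' @seealso [hertz_depth()], [sneddon_force()]
#' @export
#' @examples
#' hertz_force(300, 44.65e-6, 4e-6) # ~2.14e-8 N for the study probe
hertz_force <- function(K, radius, depth) {
  check_positive(K, "K")
  check_positive(radius, "radius")
  if (any(depth < 0)) stop("`depth` must be >= 0", call. = FALSE)
  (4 / 3) * K * sqrt(radius) * depth^1.5
}

#' Indentation depth reaching a given Hertz force
#'
#' Closed-form inverse of [hertz_force()]:
#' \eqn{\delta = (3F / (4 K \sqrt{R}))^{2/3}}.
#'
#' @inheritParams hertz_force
#' @param force Force (N), `>= 0`. Vectorised.
#' @return Depth (m).
#' @export
hertz_depth <- function(K, radius, force) {
  check_positive(K, "K")
  check_positive(radius, "radius")
  if (any(force < 0)) stop("`force` must be >= 0", call. = FALSE)
  (3 * force / (4 * K * sqrt(radius)))^(2 / 3)
}

#' Contact radius of a rigid sphere at a given indentation depth
#'
#' Solves the rigid-sphere-on-half-space relation
#' \deqn{\delta = \frac{a}{2} \ln\frac{R + a}{R - a}}
#' for the contact radius `a` by bracketed root finding on
#' `a in [0, (1 - 1e-9) R)`. The bracket guard keeps the solver away from
#' the logarithmic singularity at `a = R`. The solution is unique because
#' the right-hand side is strictly increasing in `a`.
#'
#' @inheritParams hertz_force
#' @param tol Relative tolerance of the root (default `1e-12`).
#' @return Contact radius (m), same length as `depth`; 0 where `depth` is 0.
#' @export
#' @examples
#' sneddon_contact_radius(44.65e-6, 12.26e-6) # ~R/2
sneddon_contact_radius <- function(radius, depth, tol = 1e-12) {
  check_positive(radius, "radius")
  if (any(depth < 0)) stop("`depth` must be >= 0", call. = FALSE)
  if (tol <= 0) stop("`tol` must be > 0", call. = FALSE)
  # depth grows without bound as a -> R, so any finite depth has a root,
  # but depths at or beyond R signal a non-physical deep-contact request
  if (any(depth >= radius)) {
    stop("`depth` must be < `radius`; deeper contact is outside the model's domain",
         call. = FALSE)
  }
  a_hi <- (1 - 1e-9) * radius
  vapply(depth, function(d) {
    if (d == 0) return(0)
    f <- function(a) (a / 2) * log((radius + a) / (radius - a)) - d
    out <- tryCatch(
      stats::uniroot(f, lower = 0, upper = a_hi, tol = tol * radius,
                     maxiter = 200L),
      error = function(e) {
        stop(sprintf(
          "contact-radius solver failed on bracket [0, %.6g] (depth %.6g m): %s",
          a_hi, d, conditionMessage(e)), call. = FALSE)
      })
    out$root
  }, numeric(1))
}

#' Sneddon contact force for a spherical indenter
#'
#' Exact force for a rigid sphere on an elastic half-space:
#' \deqn{F = K \left[ \frac{a^2 + R^2}{2} \ln\frac{R + a}{R - a} - a R \right],}
#' with the contact radius `a` obtained from [sneddon_contact_radius()].
#' Converges to [hertz_force()] as `depth/radius -> 0` and remains accurate
#' at deep indentation (`depth/radius >= 1/3`), where the paraboloid
#' approximation degrades.
#'
#' @inheritParams hertz_force
#' @param tol Relative tolerance passed to the contact-radius solver.
#' @return Force (N), same length as `depth`.
#' @export
sneddon_force <- function(K, radius, depth, tol = 1e-12) {
  check_positive(K, "K")
  a <- sneddon_contact_radius(radius, depth, tol = tol)
  K * (((a^2 + radius^2) / 2) * log((radius + a) / (radius - a)) - a * radius)
}

#' Indentation depth reaching a given Sneddon force
#'
#' Numerical inverse of [sneddon_force()] by bracketed root finding on the
#' depth. Provided so both contact models support depth <-> force round
#' trips.
#'
#' @inheritParams hertz_depth
#' @param tol Relative tolerance of the root.
#' @return Depth (m).
#' @export
sneddon_depth <- function(K, radius, force, tol = 1e-12) {
  check_positive(K, "K")
  check_positive(radius, "radius")
  if (any(force < 0)) stop("`force` must be >= 0", call. = FALSE)
  vapply(force, function(fi) {
    if (fi == 0) return(0)
    f <- function(d) sneddon_force(K, radius, d) - fi
    d_hi <- (1 - 1e-8) * radius
    if (f(d_hi) < 0) {
      stop("`force` exceeds the model's range at depth < radius", call. = FALSE)
    }
    stats::uniroot(f, lower = 0, upper = d_hi, tol = tol * radius,
                   maxiter = 200L)$root
  }, numeric(1))
}

#' Evaluate a contact model by name
#'
#' Dispatch helper used throughout the fitting pipeline: force at given
#' depth under `"hertz"` or `"sneddon"`.
#'
#' @inheritParams hertz_force
#' @param model `"hertz"` or `"sneddon"`.
#' @return Force (N).
#' @export
contact_force <- function(K, radius, depth, model = c("hertz", "sneddon")) {
  model <- match.arg(model)
  switch(model,
    hertz = hertz_force(K, radius, depth),
    sneddon = sneddon_force(K, radius, depth)
  )
}

#' @rdname contact_force
#' @param force Force (N).
#' @export
contact_depth <- function(K, radius, force, model = c("hertz", "sneddon")) {
  model <- match.arg(model)
  switch(model,
    hertz = hertz_depth(K, radius, force),
    sneddon = sneddon_depth(K, radius, force)
  )
}

# Model shape function g(depth) with F = K * g(depth): both models are
# linear in K, which the modulus fit exploits. For Sneddon a dense
# monotone-spline interpolant avoids a root solve per sample; nodes are
# exact solver values so interpolation error is far below fit noise.
contact_shape_fun <- function(radius, model, depth_max, n_nodes = 512L) {
  if (model == "hertz") {
    force(radius)
    return(function(d) (4 / 3) * sqrt(radius) * d^1.5)
  }
  depth_max <- min(max(depth_max, radius * 1e-6), 0.95 * radius)
  # sqrt spacing concentrates nodes at shallow depth where curvature is high
  dd <- depth_max * seq(0, 1, length.out = n_nodes)^2
  g <- sneddon_force(1, radius, dd)
  sf <- stats::splinefun(dd, g, method = "hyman")
  function(d) {
    out <- sf(pmin(d, depth_max))
    over <- d > depth_max
    if (any(over)) out[over] <- sneddon_force(1, radius, d[over])
    pmax(out, 0)
  }
}

check_positive <- function(x, name) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(sprintf("`%s` must be finite and > 0", name), call. = FALSE)
  }
  invisible(x)
}
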