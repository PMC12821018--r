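#' Compartment response model for the synthetic tissue phantom
#'
#' Parametric ground-truth dependence of the true modulus on the
#' measurement condition, as a product of four factors applied to the
#' compartment's base modulus:
#' \itemize{
#' \item force/speed stiffening: `(1 + A_f (1 - exp(-F/F_c))) *
#'   (1 + A_s (1 - exp(-s/s_c)))` — saturating exponentials, so effects are
#'   strongest at the low end of the force/speed range;
#' \item postmortem softening: a smooth logistic plateau-decline-plateau in
#'   time, level 1 before `t_on`, settling at `f_end` after `t_off`;
#' \item temperature: linear with relative slope `rho` (%/degree C)
#'   anchored at 38 degrees C (rat body temperature), i.e.
#'   `1 + rho/100 * (T - 38)`.
#' }
#'
#' Defaults encode the study system's qualitative behaviour: gray matter
#' holds its stiffness until ~3 h postmortem then declines to ~2/3 of its
#' starting value by ~6 h; white matter declines from the start to ~1/2 by
#' ~6 h; both compartments soften by ~3.9 and ~3.7 %/degree C respectively;
#' white matter stiffens more strongly with force and speed than gray, so
#' the gray-to-white ratio falls toward 1 along those axes.
#'
#' @param A_f,F_c Force-stiffening amplitude (dimensionless) and saturation
#'   force (N).
#' @param A_s,s_c Speed-stiffening amplitude and saturation speed (m/s).
#' @param t_on,t_off Onset and end of the postmortem decline (h).
#' @param f_end Terminal fraction of the starting modulus, in `(0, 1]`.
#' @param rho Relative temperature slope (%/degree C).
#' @return A `response_model` list.
#' @export
response_model <- function(A_f = 0.5, F_c = 300e-9, A_s = 0.3, s_c = 400e-6,
                           t_on = 3, t_off = 6, f_end = 2 / 3, rho = -3.9) {
  if (f_end <= 0 || f_end > 1) stop("`f_end` must be in (0, 1]", call. = FALSE)
  if (t_off <= t_on) stop("`t_off` must exceed `t_on`", call. = FALSE)
  check_positive(F_c, "F_c"); check_positive(s_c, "s_c")
  structure(list(A_f = A_f, F_c = F_c, A_s = A_s, s_c = s_c,
                 t_on = t_on, t_off = t_off, f_end = f_end, rho = rho),
            class = "response_model")
}

#' @rdname response_model
#' @param resp A `response_model`.
#' @param force,speed,t_pm,temperature Condition: setpoint force (N), speed
#'   (m/s), postmortem time (h), temperature (degree C). Vectorised.
#' @return `response_factor()`: the dimensionless multiplier on the base
#'   modulus, continuous in all arguments.
#' @export
response_factor <- function(resp, force, speed, t_pm, temperature) {
  stopifnot(inherits(resp, "response_model"))
  t_mid <- (resp$t_on + resp$t_off) / 2
  w <- (resp$t_off - resp$t_on) / 8  # logistic width: ~plateau outside [t_on, t_off]
  pm <- resp$f_end + (1 - resp$f_end) / (1 + exp((t_pm - t_mid) / w))
  fac <- (1 + resp$A_f * (1 - exp(-force / resp$F_c))) *
    (1 + resp$A_s * (1 - exp(-speed / resp$s_c))) *
    pm *
    (1 + resp$rho / 100 * (temperature - 38))
  if (any(fac <= 0)) {
    stop("response factor is non-positive somewhere on the requested condition",
         call. = FALSE)
  }
  fac
}

ellipse_poly <- function(cx, cy, rx, ry, n = 96L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(x = cx + rx * cos(th), y = cy + ry * sin(th))
}

#' Build a two-compartment tissue phantom
#'
#' A synthetic spinal-cord cross-section: an outer outline polygon (white
#' matter) with one or two interior gray-matter ellipses, a simplified
#' stand-in for the gray-matter "butterfly". Three presets mimic the three
#' anatomical sectioning planes; they differ in geometry and in base
#' moduli (reflecting the plane dependence of the measured ratio).
#' Dimensions are metres; a transverse rat cervical section is a few mm
#' across.
#'
#' @param preset `"transverse"`, `"horizontal"` or `"sagittal"`.
#' @param K_g0,K_w0 Base moduli (Pa) of gray and white matter at the
#'   reference condition (zero-force/zero-speed limit, fresh tissue at
#'   38 degrees C). Defaults give transverse gray-to-white ratios of a few
#'   at low force, dropping toward 1 at high force/speed.
#' @param response_gray,response_white Per-compartment [response_model()]s.
#' @return A `tissue_phantom` list: `outline` (polygon matrix), `gray`
#'   (list of polygon matrices), `K0` (named base moduli), `response`
#'   (named list), `preset`.
#' @export
make_phantom <- function(preset = c("transverse", "horizontal", "sagittal"),
                         K_g0 = 230, K_w0 = 47,
                         response_gray = response_model(
                           A_f = 0.4, A_s = 0.25, t_on = 3, t_off = 6,
                           f_end = 2 / 3, rho = -3.9),
                         response_white = response_model(
                           A_f = 2.5, A_s = 1.0, t_on = 0.01, t_off = 6,
                           f_end = 1 / 2, rho = -3.7)) {
  preset <- match.arg(preset)
  check_positive(K_g0, "K_g0"); check_positive(K_w0, "K_w0")
  stopifnot(inherits(response_gray, "response_model"),
            inherits(response_white, "response_model"))
  mm <- 1e-3
  geom <- switch(preset,
    transverse = list(
      outline = ellipse_poly(0, 0, 1.7 * mm, 1.2 * mm),
      gray = list(ellipse_poly(-0.45 * mm, 0, 0.5 * mm, 0.7 * mm),
                  ellipse_poly(0.45 * mm, 0, 0.5 * mm, 0.7 * mm))),
    horizontal = list(
      outline = ellipse_poly(0, 0, 4 * mm, 1.5 * mm),
      gray = list(ellipse_poly(0, 0, 3.2 * mm, 0.55 * mm))),
    sagittal = list(
      outline = ellipse_poly(0, 0, 4 * mm, 1.3 * mm),
      gray = list(ellipse_poly(0, 0, 3.2 * mm, 0.45 * mm))))
  structure(
    list(outline = geom$outline, gray = geom$gray,
         K0 = c(gray = K_g0, white = K_w0),
         response = list(gray = response_gray, white = response_white),
         preset = preset),
    class = "tissue_phantom")
}

#' @export
print.tissue_phantom <- function(x, ...) {
  cat(sprintf("<tissue_phantom> %s preset, K_g0 = %.3g Pa, K_w0 = %.3g Pa\n",
              x$preset, x$K0["gray"], x$K0["white"]))
  invisible(x)
}

in_poly <- function(x, y, poly) {
  pracma::inpolygon(x, y, poly[, 1], poly[, 2], boundary = TRUE)
}

#' Compartment label of a phantom position
#'
#' @param phantom A [make_phantom()] phantom.
#' @param x,y Position (m). Vectorised.
#' @return `"gray"` or `"white"` per position; positions outside the
#'   outline are an error.
#' @export
phantom_compartment <- function(phantom, x, y) {
  stopifnot(inherits(phantom, "tissue_phantom"))
  inside <- in_poly(x, y, phantom$outline)
  if (any(!inside)) {
    stop(sprintf("%d position(s) fall outside the phantom outline",
                 sum(!inside)), call. = FALSE)
  }
  gray <- Reduce(`|`, lapply(phantom$gray, function(p) in_poly(x, y, p)))
  ifelse(gray, "gray", "white")
}

#' Ground-truth modulus of a phantom at a position and condition
#'
#' Resolves the compartment by point-in-polygon and multiplies the
#' compartment's base modulus by its [response_factor()] at the given
#' measurement condition.
#'
#' @inheritParams phantom_compartment
#' @inheritParams response_factor
#' @return True K (Pa), vectorised over positions.
#' @export
true_modulus <- function(phantom, x, y, force = 30e-9, speed = 20e-6,
                         t_pm = 1.5, temperature = 38) {
  comp <- phantom_compartment(phantom, x, y)
  n <- length(comp)
  force <- rep_len(force, n); speed <- rep_len(speed, n)
  t_pm <- rep_len(t_pm, n); temperature <- rep_len(temperature, n)
  K0 <- unname(phantom$K0[comp])
  fac <- numeric(n)
  for (cc in unique(comp)) {
    i <- comp == cc
    fac[i] <- response_factor(phantom$response[[cc]], force[i], speed[i],
                              t_pm[i], temperature[i])
  }
  K0 * fac
}
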