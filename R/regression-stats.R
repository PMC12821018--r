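#' Compare a linear model against a horizontal line
#'
#' The temperature (or time) regression used for per-compartment medians:
#' ordinary least squares of `y = a x + b` (alternative) against the
#' constant `y = c` (null, the mean), compared with an extra-sum-of-squares
#' F-test,
#' \deqn{F = \frac{(RSS_0 - RSS_1)/1}{RSS_1/(n - 2)},}
#' with p from the F distribution on (1, n-2) degrees of freedom. The
#' linear model is preferred when `p < alpha`. The adjusted r-squared uses
#' the alternative model's n-2 residual degrees of freedom:
#' `1 - (1 - r2)(n - 1)/(n - 2)`.
#'
#' @param data Data frame holding the regression points (typically one
#'   per-map median per row).
#' @param x,y Column names (strings) of predictor (degree C or h) and
#'   response (Pa or dimensionless ratio).
#' @param alpha Significance level (default 0.05).
#' @return A `model_comparison` object; see [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods.
#' @export
#' @examples
#' d <- data.frame(temp = c(20, 25, 30, 35, 38), K = c(320, 280, 250, 230, 228))
#' fit <- fit_linear_vs_constant(d, "temp", "K")
#' glance(fit)
fit_linear_vs_constant <- function(data, x, y, alpha = 0.05) {
  xx <- data[[x]]; yy <- data[[y]]
  if (is.null(xx) || is.null(yy)) stop("`x`/`y` columns not found", call. = FALSE)
  ok <- is.finite(xx) & is.finite(yy)
  xx <- xx[ok]; yy <- yy[ok]
  n <- length(xx)
  if (n < 3) stop("need at least 3 finite points", call. = FALSE)
  if (diff(range(xx)) == 0) {
    stop("degenerate design: `x` is constant", call. = FALSE)
  }
  lin <- stats::lm(yy ~ xx)
  rss_alt <- sum(stats::residuals(lin)^2)
  rss_null <- sum((yy - mean(yy))^2)
  f_stat <- ((rss_null - rss_alt) / 1) / (rss_alt / (n - 2))
  p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  r2 <- 1 - rss_alt / rss_null
  structure(
    list(slope = unname(stats::coef(lin)[2]),
         intercept = unname(stats::coef(lin)[1]),
         constant = mean(yy), rss_null = rss_null, rss_alt = rss_alt,
         f_statistic = f_stat, p_value = p,
         adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
         preferred = if (p < alpha) "linear" else "horizontal",
         alpha = alpha, n = n, lm_fit = lin,
         data = tibble::tibble(x = xx, y = yy),
         x_name = x, y_name = y),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat(sprintf(
    paste0("<model_comparison> n = %d\n",
           "  linear:     y = %.4g x + %.4g\n",
           "  horizontal: y = %.4g\n",
           "  F(1, %d) = %.4g, p = %.3g -> preferred: %s\n",
           "  adjusted r^2 = %.3f\n"),
    x$n, x$slope, x$intercept, x$constant, x$n - 2, x$f_statistic,
    x$p_value, x$preferred, x$adj_r_squared))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname fit_linear_vs_constant
#' @param x A `model_comparison` object.
#' @param ... Unused.
#' @method tidy model_comparison
#' @export
tidy.model_comparison <- function(x, ...) {
  s <- summary(x$lm_fit)$coefficients
  tibble::tibble(term = c("intercept", "slope", "constant"),
                 estimate = c(x$intercept, x$slope, x$constant),
                 std.error = c(s[1, 2], s[2, 2], NA_real_))
}

#' @rdname fit_linear_vs_constant
#' @method glance model_comparison
#' @export
glance.model_comparison <- function(x, ...) {
  tibble::tibble(n = x$n, slope = x$slope, intercept = x$intercept,
                 constant = x$constant, rss_null = x$rss_null,
                 rss_alt = x$rss_alt, f_statistic = x$f_statistic,
                 p_value = x$p_value, adj_r_squared = x$adj_r_squared,
                 preferred = x$preferred)
}

#' Relative slope of a temperature regression
#'
#' Normalises the fitted slope by the predicted response at a reference
#' temperature (default 38 degrees C, rat body temperature):
#' `relative_slope = 100 * a / (a * T_ref + b)` in %/degree C. This makes
#' compartments with different absolute stiffness comparable.
#'
#' @param object A `model_comparison` from [fit_linear_vs_constant()], or
#'   a numeric slope (Pa/degree C) with `intercept` or `predicted` given.
#' @param t_ref Reference temperature (degree C), default 38.
#' @param intercept Intercept b (Pa), used when `object` is a bare slope.
#' @param predicted Directly supplied predicted response at `t_ref` (Pa);
#'   overrides `intercept`.
#' @param ... Unused.
#' @return A tibble `t_ref_c`, `predicted_at_ref`, `relative_slope_pct`.
#' @export
#' @examples
#' relative_slope(-9.0, predicted = 231.4) # -3.89 %/degree C
relative_slope <- function(object, t_ref = 38, ...) {
  UseMethod("relative_slope")
}

#' @rdname relative_slope
#' @export
relative_slope.model_comparison <- function(object, t_ref = 38, ...) {
  relative_slope(object$slope, t_ref = t_ref, intercept = object$intercept)
}

#' @rdname relative_slope
#' @export
relative_slope.numeric <- function(object, t_ref = 38, intercept = NULL,
                                   predicted = NULL, ...) {
  slope <- object
  pred <- if (!is.null(predicted)) predicted else {
    if (is.null(intercept)) {
      stop("supply `intercept` or `predicted`", call. = FALSE)
    }
    slope * t_ref + intercept
  }
  if (pred <= 0) {
    stop("predicted response at the reference temperature is not positive",
         call. = FALSE)
  }
  tibble::tibble(t_ref_c = t_ref, predicted_at_ref = pred,
                 relative_slope_pct = 100 * slope / pred)
}

#' Nominal strain of an indentation
#'
#' Engineering-strain estimate `epsilon = delta / h`: the indentation
#' depth over the sample height (999 um sections in the study), the
#' length-change-over-original-length approximation for the bulk sample.
#' Local strains under the probe are higher; this is the nominal figure
#' used to place AFM settings on a strain axis.
#'
#' @param delta Indentation depth (m), `>= 0`. Vectorised.
#' @param height Sample height (m), `> 0`.
#' @return A tibble `delta_m`, `height_m`, `strain`, `strain_pct`.
#' @export
#' @examples
#' nominal_strain(40e-6, 999e-6)$strain_pct # ~4.0
nominal_strain <- function(delta, height) {
  check_positive(height, "height")
  if (any(delta < 0)) stop("`delta` must be >= 0", call. = FALSE)
  eps <- delta / height
  tibble::tibble(delta_m = delta, height_m = height, strain = eps,
                 strain_pct = 100 * eps)
}

#' Strain rate of an indentation ramp
#'
#' One indentation of duration `t_delta` is treated as half an oscillation
#' period, giving `rate = 1 / (2 t_delta)` in Hz. Study indentation
#' durations of 8-1278 ms correspond to ~0.4-60 Hz.
#'
#' @param t_delta Indentation duration (s), `> 0`. Vectorised.
#' @return A tibble `t_delta_s`, `strain_rate_hz`.
#' @export
#' @examples
#' strain_rate(1.278)$strain_rate_hz # ~0.39
strain_rate <- function(t_delta) {
  check_positive(t_delta, "t_delta")
  tibble::tibble(t_delta_s = t_delta, strain_rate_hz = 1 / (2 * t_delta))
}

#' Correlation between modulus K and stiffness k
#'
#' Pearson correlation between the model-derived modulus K and the
#' model-free stiffness k across a set of curves, with the OLS line of k
#' on K. High correlation indicates the modulus ranking does not hinge on
#' the contact model.
#'
#' @param data Data frame of paired values.
#' @param K,k Column names (strings); defaults match [fit_curves()] output.
#' @return A tibble `pearson_r`, `slope`, `intercept`, `n`.
#' @export
correlate_K_k <- function(data, K = "K_pa", k = "k_n_per_m") {
  KK <- data[[K]]; kk <- data[[k]]
  ok <- is.finite(KK) & is.finite(kk)
  KK <- KK[ok]; kk <- kk[ok]
  if (length(KK) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(KK) == 0 || stats::sd(kk) == 0) {
    stop("degenerate: zero variance in K or k", call. = FALSE)
  }
  fit <- stats::lm(kk ~ KK)
  tibble::tibble(pearson_r = stats::cor(KK, kk),
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 n = length(KK))
}
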