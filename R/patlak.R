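#' Patlak plot coordinates
#'
#' Transforms a tissue concentration curve and its plasma input into the
#' Patlak graphical coordinates: normalized integrated plasma exposure
#' \eqn{x_j = \int_0^{t_j} C_p\,d\tau / C_p(t_j)} (min) against the
#' volume-of-distribution ratio \eqn{y_j = C_t(t_j)/C_p(t_j)}. Under
#' irreversible uptake the points fall on a line with slope \eqn{K_i} and
#' intercept \eqn{v_p}.
#'
#' The plasma integral is evaluated analytically for [vif_model()] inputs,
#' piecewise (trapezoid over the measured segment, analytic
#' mono-exponential tail) for [fit_plasma_model()] objects, and by dense
#' trapezoid quadrature for a measured curve or bare function.
#'
#' @param curve_t Tissue concentration curve: tibble with `time`, `conc`.
#' @param plasma Plasma input: a [vif_model()], a [fit_plasma_model()]
#'   result, a measured curve (tibble `time`, `conc`), or a function.
#' @param grid_step Quadrature step (min) when no analytic integral exists.
#' @return A tibble with columns `x` (min) and `y` (dimensionless).
#' @export
patlak_coords <- function(curve_t, plasma, grid_step = 0.5 / 60) {
  curve_t <- validate_curve(curve_t)
  times <- curve_t$time
  if (inherits(plasma, "vif_model")) {
    cp <- vif_eval(plasma, times)
    cp_int <- vif_integral(plasma, times)
  } else if (inherits(plasma, "plasma_model")) {
    cp <- plasma_eval(plasma, times)
    cp_int <- plasma_integral(plasma, times)
  } else {
    cp_fun <- as_cp_function(plasma)
    cp <- cp_fun(times)
    cp_int <- vapply(times, function(tt) {
      g <- sort(unique(c(seq(0, tt, by = grid_step), tt)))
      f <- cp_fun(g)
      sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
    }, numeric(1))
  }
  bad <- cp <= 0
  if (any(bad)) {
    stop(sprintf(
      "plasma concentration is non-positive at t = %s min; Patlak coordinates undefined.",
      paste(format(times[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  tibble::tibble(x = cp_int / cp, y = curve_t$conc / cp)
}

#' Fit a Patlak regression line
#'
#' Ordinary (unweighted) least-squares line through Patlak points; the
#' slope estimates the leakage rate \eqn{K_i} (1/min) and the intercept
#' the fractional plasma volume \eqn{v_p}. With exactly two points the
#' line interpolates them.
#'
#' @param points Tibble with columns `x` and `y` (from [patlak_coords()]).
#' @return An object of class `patlak_fit` with elements `ki`, `vp`,
#'   `n_points`, `rss`, and the `points` used.
#' @examples
#' pts <- tibble::tibble(x = c(5, 10, 20), y = 8e-4 * c(5, 10, 20) + 0.049)
#' patlak_fit(pts)
#' @export
patlak_fit <- function(points) {
  if (!is.data.frame(points) || !all(c("x", "y") %in% names(points))) {
    stop("`points` needs `x` and `y` columns.", call. = FALSE)
  }
  x <- points$x
  y <- points$y
  if (length(x) < 2) stop("need at least 2 Patlak points.", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) {
    stop("all Patlak x values are equal; the fit is singular.", call. = FALSE)
  }
  ki <- sum((x - mean(x)) * (y - mean(y))) / sxx
  vp <- mean(y) - ki * mean(x)
  resid <- y - (vp + ki * x)
  structure(
    list(ki = ki, vp = vp, n_points = length(x), rss = sum(resid^2),
         points = tibble::tibble(x = x, y = y)),
    class = "patlak_fit"
  )
}

#' @export
print.patlak_fit <- function(x, ...) {
  cat(sprintf("<patlak_fit> Ki = %.4g /min, vp = %.4g (%d points, RSS %.3g)\n",
              x$ki, x$vp, x$n_points, x$rss))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.patlak_fit <- function(x, ...) {
  tibble::tibble(
    term = c("ki", "vp"),
    estimate = c(x$ki, x$vp),
    units = c("1/min", "")
  )
}

#' @exportS3Method generics::glance
glance.patlak_fit <- function(x, ...) {
  tibble::tibble(n_points = x$n_points, rss = x$rss)
}

#' @exportS3Method ggplot2::autoplot
autoplot.patlak_fit <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_abline(slope = object$ki, intercept = object$vp,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Normalized plasma exposure (min)",
      y = expression(C[t] / C[p]),
      title = sprintf("Patlak fit: Ki = %.3g /min, vp = %.3g",
                      object$ki, object$vp)
    )
}
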