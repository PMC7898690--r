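#' Parametric vascular input function
#'
#' Constructs a parametric plasma concentration-time function \eqn{C_p(t)}:
#' zero before the injection start `t0`, a bolus rise from `t0` to the peak
#' time `t_peak`, and a mono-exponential washout
#' \eqn{a_{peak} e^{-m (t - t_{peak})}} afterwards. The curve is continuous
#' at the peak. Defaults emulate a slow-infusion venous (superior sagittal
#' sinus) curve with the bolus peak at 0.93 min (the 30th volume of a
#' 1.86-s dynamic series) and a slow washout.
#'
#' @param t0 Injection start time (min). Time zero of the analysis.
#' @param t_peak Bolus peak time (min), must exceed `t0`.
#' @param a_peak Peak plasma concentration (mM).
#' @param m Washout rate (1/min), non-negative.
#' @param shape Rise shape, `"linear"` or `"gamma"` (a gamma-variate rise
#'   \eqn{(\tau/\tau_p)^2 e^{2(1 - \tau/\tau_p)}} scaled to peak at
#'   `a_peak`).
#' @return An object of class `vif_model`.
#' @examples
#' vif <- vif_model()
#' vif_eval(vif, c(0, 0.5, 1, 10))
#' @export
vif_model <- function(t0 = 0, t_peak = 0.93, a_peak = 1.5, m = 0.03,
                      shape = c("linear", "gamma")) {
  shape <- match.arg(shape)
  stopifnot(is.numeric(t0), is.numeric(t_peak), is.numeric(a_peak), is.numeric(m))
  if (t_peak <= t0) stop("`t_peak` must be greater than `t0`.", call. = FALSE)
  if (a_peak <= 0) stop("`a_peak` must be positive.", call. = FALSE)
  if (m < 0) stop("washout rate `m` must be non-negative.", call. = FALSE)
  structure(
    list(t0 = t0, t_peak = t_peak, a_peak = a_peak, m = m, shape = shape),
    class = "vif_model"
  )
}

#' @export
print.vif_model <- function(x, ...) {
  cat(sprintf(
    "<vif_model> %s rise: t0 = %g min, peak %g mM at %g min, washout %g /min\n",
    x$shape, x$t0, x$a_peak, x$t_peak, x$m
  ))
  invisible(x)
}

# dimensionless rise profile on tau = (t - t0)/(t_peak - t0) in [0, 1]
vif_rise_profile <- function(tau, shape) {
  switch(shape,
    linear = tau,
    gamma = tau^2 * exp(2 * (1 - tau))
  )
}

#' Evaluate a vascular input function
#'
#' @param vif A [vif_model()].
#' @param t Times (min).
#' @return Plasma concentration (mM) at each time.
#' @export
vif_eval <- function(vif, t) {
  stopifnot(inherits(vif, "vif_model"), is.numeric(t))
  out <- numeric(length(t))
  rising <- t > vif$t0 & t <= vif$t_peak
  washing <- t > vif$t_peak
  tau <- (t[rising] - vif$t0) / (vif$t_peak - vif$t0)
  out[rising] <- vif$a_peak * vif_rise_profile(tau, vif$shape)
  out[washing] <- vif$a_peak * exp(-vif$m * (t[washing] - vif$t_peak))
  out
}

#' Running integral of a vascular input function
#'
#' \eqn{\int_0^t C_p(\tau)\,d\tau} in mM.min. The washout segment is
#' integrated analytically; the rise segment analytically for the linear
#' shape and by fine trapezoid quadrature for the gamma shape.
#'
#' @inheritParams vif_eval
#' @return Integral values, same length as `t`.
#' @export
vif_integral <- function(vif, t) {
  stopifnot(inherits(vif, "vif_model"), is.numeric(t))
  rise_len <- vif$t_peak - vif$t0
  rise_area_to <- function(tt) {
    # integral of the rise profile from t0 to tt (tt clamped to the rise)
    tau <- pmin(pmax((tt - vif$t0) / rise_len, 0), 1)
    if (vif$shape == "linear") {
      vif$a_peak * rise_len * tau^2 / 2
    } else {
      vapply(tau, function(u) {
        if (u <= 0) return(0)
        g <- seq(0, u, length.out = 513)
        f <- vif_rise_profile(g, vif$shape)
        vif$a_peak * rise_len * sum(diff(g) * (f[-1] + f[-length(f)]) / 2)
      }, numeric(1))
    }
  }
  out <- rise_area_to(t)
  washing <- t > vif$t_peak
  if (any(washing)) {
    full_rise <- rise_area_to(vif$t_peak)
    dtw <- t[washing] - vif$t_peak
    tail_area <- if (vif$m > 0) {
      vif$a_peak / vif$m * (1 - exp(-vif$m * dtw))
    } else {
      vif$a_peak * dtw
    }
    out[washing] <- full_rise + tail_area
  }
  out
}

# Resolve a plasma-input argument into an evaluator function(t) -> mM.
# Accepts a vif_model, a plasma_model, a bare function, or a concentration
# curve (tibble with time/conc), the latter linearly interpolated.
as_cp_function <- function(cp) {
  if (inherits(cp, "vif_model")) {
    function(t) vif_eval(cp, t)
  } else if (inherits(cp, "plasma_model")) {
    function(t) plasma_eval(cp, t)
  } else if (is.function(cp)) {
    cp
  } else if (is.data.frame(cp)) {
    curve <- validate_curve(cp)
    function(t) {
      if (any(t < curve$time[1] - 1e-9 | t > curve$time[nrow(curve)] + 1e-9)) {
        stop("requested time outside the plasma curve's support.", call. = FALSE)
      }
      stats::approx(curve$time, curve$conc, xout = t, rule = 2)$y
    }
  } else {
    stop("cannot interpret plasma input of class ",
         paste(class(cp), collapse = "/"), call. = FALSE)
  }
}
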