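#' Relaxation constants
#'
#' The contrast-agent longitudinal relaxivity and the hematocrit used to
#' convert T1 changes to concentration and whole-blood concentration to
#' plasma concentration. Defaults are the 7 T values r1 = 4.2 /mM/s and
#' Hct = 0.45.
#'
#' @param r1 Longitudinal relaxivity (1/mM/s), positive.
#' @param hct Hematocrit fraction, in `[0, 1)`.
#' @return An object of class `relaxation_constants`.
#' @export
relaxation_constants <- function(r1 = 4.2, hct = 0.45) {
  stopifnot(is.numeric(r1), is.numeric(hct))
  if (r1 <= 0) stop("`r1` must be positive.", call. = FALSE)
  if (hct < 0 || hct >= 1) stop("`hct` must be in [0, 1).", call. = FALSE)
  structure(list(r1 = r1, hct = hct), class = "relaxation_constants")
}

#' @export
print.relaxation_constants <- function(x, ...) {
  cat(sprintf("<relaxation_constants> r1 = %g /mM/s, Hct = %g\n", x$r1, x$hct))
  invisible(x)
}

#' Convert a T1 change to contrast-agent concentration
#'
#' The change in longitudinal relaxation rate is linearly related to the
#' concentration: \eqn{C = (1/T_{1,post} - 1/T_{1,pre}) / r_1}, with T1 in
#' seconds and r1 in 1/mM/s, so C is in mM. Element-wise over arrays.
#' Negative concentrations (from noise) are retained. Non-positive T1
#' values yield `NA` with a warning rather than propagating silently.
#'
#' @param t1_pre Precontrast T1 (s), scalar or array.
#' @param t1_post Postcontrast T1 (s), same shape.
#' @param consts A [relaxation_constants()].
#' @return Concentration (mM), same shape as the inputs.
#' @examples
#' t1_to_concentration(2.0, 1.8, relaxation_constants())
#' @export
t1_to_concentration <- function(t1_pre, t1_post, consts = relaxation_constants()) {
  stopifnot(inherits(consts, "relaxation_constants"))
  bad <- (!is.na(t1_pre) & t1_pre <= 0) | (!is.na(t1_post) & t1_post <= 0)
  if (any(bad)) {
    warning(sum(bad), " non-positive T1 value(s) set to NA.", call. = FALSE)
  }
  out <- (1 / t1_post - 1 / t1_pre) / consts$r1
  out[bad] <- NA_real_
  out
}

# forward map used by the phantom: T1 after adding concentration C
concentration_to_t1 <- function(t1_pre, conc, consts = relaxation_constants()) {
  1 / (1 / t1_pre + consts$r1 * conc)
}

#' Convert whole-blood to plasma concentration
#'
#' Contrast agent is confined to plasma, so the whole-blood concentration
#' measured in a vessel is corrected for the cellular fraction:
#' \eqn{C_p = C_b / (1 - Hct)}.
#'
#' @param cb Whole-blood concentration (mM), scalar or vector.
#' @param consts A [relaxation_constants()].
#' @return Plasma concentration (mM).
#' @export
blood_to_plasma <- function(cb, consts = relaxation_constants()) {
  stopifnot(inherits(consts, "relaxation_constants"))
  if (consts$hct >= 1) stop("`hct` must be below 1.", call. = FALSE)
  cb / (1 - consts$hct)
}

#' Mono-exponential decay fit
#'
#' Fits \eqn{C(t) = A e^{-m t}} by least squares on log-concentration
#' (log-linear regression), the deterministic closed form adequate for the
#' three-point plasma tails this package fits. The rate is clamped at zero
#' (no growing tails); a clamp is flagged in the result.
#'
#' @param times Sample times (min), at least two.
#' @param conc Concentrations (mM), all positive.
#' @return A list with `amplitude` (mM), `rate` (1/min), and `clamped`.
#' @examples
#' monoexp_fit(c(3, 10, 25), 1.2 * exp(-0.04 * c(3, 10, 25)))
#' @export
monoexp_fit <- function(times, conc) {
  stopifnot(is.numeric(times), is.numeric(conc), length(times) == length(conc))
  if (length(times) < 2) stop("need at least 2 points.", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc <= 0)) {
    stop("all concentrations must be positive for a log-domain fit.",
         call. = FALSE)
  }
  ly <- log(conc)
  sxx <- sum((times - mean(times))^2)
  if (sxx <= 0) stop("times must not all be equal.", call. = FALSE)
  slope <- sum((times - mean(times)) * (ly - mean(ly))) / sxx
  rate <- -slope
  clamped <- FALSE
  if (rate < 0) {
    # flat fit: with m fixed at 0 the log-domain LS amplitude is the
    # geometric mean of the concentrations
    rate <- 0
    clamped <- TRUE
    amplitude <- exp(mean(ly))
  } else {
    amplitude <- exp(mean(ly) + rate * mean(times))
  }
  list(amplitude = amplitude, rate = rate, clamped = clamped)
}
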