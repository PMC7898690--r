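#' Extract a blood concentration curve from a dynamic series
#'
#' Spatial mean over a vessel region of interest (e.g. a few voxels in the
#' superior sagittal sinus) at each time point of a 4D dynamic series.
#'
#' @param dynamic 4D array (x, y, z, time) of whole-blood concentration (mM).
#' @param roi_mask A [volume_image()] or logical array marking the vessel
#'   ROI; must match the spatial grid.
#' @param times Time stamps of the volumes (min). Default: 1.86-s spacing
#'   starting at 0.
#' @return A tibble with `time` (min) and `conc` (mM).
#' @export
extract_blood_curve <- function(dynamic, roi_mask,
                                times = (seq_len(dim(dynamic)[4]) - 1) * 1.86 / 60) {
  if (length(dim(dynamic)) != 4) stop("`dynamic` must be 4D.", call. = FALSE)
  if (!identical(dim(dynamic)[1:3], dim(roi_mask)[1:3])) {
    stop(sprintf("mask grid %s does not match series grid %s.",
                 paste(dim(roi_mask), collapse = "x"),
                 paste(dim(dynamic)[1:3], collapse = "x")), call. = FALSE)
  }
  if (length(times) != dim(dynamic)[4]) {
    stop("`times` must have one entry per volume.", call. = FALSE)
  }
  idx <- mask_indices(roi_mask)
  nvox <- prod(dim(dynamic)[1:3])
  mat <- matrix(dynamic, nrow = nvox)[idx, , drop = FALSE]
  tibble::tibble(time = times, conc = colMeans(mat))
}

#' Fit the piecewise plasma model
#'
#' The plasma input for the sparse protocol: the measured dynamic-series
#' blood curve up to its last time point `t_switch`, continued by a
#' mono-exponential tail fitted through the last dynamic point and the
#' blood concentrations derived from the postcontrast T1 maps. All
#' blood-derived concentrations are hematocrit-corrected to plasma before
#' fitting.
#'
#' @param dynamic_blood Whole-blood dynamic curve: tibble `time`, `conc`.
#' @param map_blood_points Tibble with `time` (min) and `conc`
#'   (whole-blood mM) for the T1-map-derived vessel points (>= 2 rows if
#'   the tail is to be determined by more than the dynamic endpoint; at
#'   least 1 required).
#' @param consts A [relaxation_constants()] supplying the hematocrit.
#' @return An object of class `plasma_model`: `measured` (plasma-unit
#'   curve), `tail_amplitude` (mM), `tail_rate` (1/min), `t_switch` (min),
#'   `clamped`.
#' @export
fit_plasma_model <- function(dynamic_blood, map_blood_points,
                             consts = relaxation_constants()) {
  dynamic_blood <- validate_curve(dynamic_blood)
  if (!is.data.frame(map_blood_points) ||
      !all(c("time", "conc") %in% names(map_blood_points)) ||
      nrow(map_blood_points) < 1) {
    stop("`map_blood_points` needs >= 1 rows with `time` and `conc`.",
         call. = FALSE)
  }
  measured <- dynamic_blood
  measured$conc <- blood_to_plasma(measured$conc, consts)
  t_switch <- measured$time[nrow(measured)]
  fit_t <- c(t_switch, map_blood_points$time)
  fit_c <- c(measured$conc[nrow(measured)],
             blood_to_plasma(map_blood_points$conc, consts))
  if (any(fit_c <= 0)) {
    stop("non-positive blood concentration among the tail fit points.",
         call. = FALSE)
  }
  tail <- monoexp_fit(fit_t, fit_c)
  structure(
    list(measured = measured, tail_amplitude = tail$amplitude,
         tail_rate = tail$rate, t_switch = t_switch, clamped = tail$clamped),
    class = "plasma_model"
  )
}

#' @export
print.plasma_model <- function(x, ...) {
  cat(sprintf(
    "<plasma_model> %d measured points to %.3g min; tail %.3g mM * exp(-%.3g t)%s\n",
    nrow(x$measured), x$t_switch, x$tail_amplitude, x$tail_rate,
    if (x$clamped) " [rate clamped at 0]" else ""))
  invisible(x)
}

#' Evaluate the plasma model
#'
#' Linear interpolation of the measured segment up to `t_switch`, then the
#' analytic mono-exponential tail.
#'
#' @param model A [fit_plasma_model()] result.
#' @param t Times (min).
#' @return Plasma concentration (mM).
#' @export
plasma_eval <- function(model, t) {
  stopifnot(inherits(model, "plasma_model"))
  out <- numeric(length(t))
  early <- t <= model$t_switch
  if (any(early)) {
    out[early] <- stats::approx(model$measured$time, model$measured$conc,
                                xout = t[early], rule = 2)$y
  }
  out[!early] <- model$tail_amplitude * exp(-model$tail_rate * t[!early])
  out
}

#' Running integral of the plasma model
#'
#' Trapezoid over the measured segment plus the analytic integral of the
#' mono-exponential tail beyond `t_switch`. Times before the first
#' measured sample assume a start from the first sample's value at its
#' own time (the measured curve is expected to begin at injection).
#'
#' @inheritParams plasma_eval
#' @return \eqn{\int_0^t C_p\,d\tau} (mM.min).
#' @export
plasma_integral <- function(model, t) {
  stopifnot(inherits(model, "plasma_model"))
  mt <- model$measured$time
  mc <- model$measured$conc
  cum <- c(0, cumsum(diff(mt) * (mc[-1] + mc[-length(mc)]) / 2))
  cum_at <- function(tt) stats::approx(mt, cum, xout = pmin(tt, model$t_switch),
                                       rule = 2)$y
  out <- cum_at(t)
  late <- t > model$t_switch
  if (any(late)) {
    a <- model$tail_amplitude
    m <- model$tail_rate
    tail_int <- if (m > 0) {
      a / m * (exp(-m * model$t_switch) - exp(-m * t[late]))
    } else {
      a * (t[late] - model$t_switch)
    }
    out[late] <- cum[length(cum)] + tail_int
  }
  out
}
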